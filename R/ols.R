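#' Constrained ordinary least squares
#'
#' Minimizes the residual sum of squares subject to `C theta = 0` by
#' unconstrained OLS on the reduced design `Z = X Q`, where `Q` spans the
#' null space of `C`.  The finite-sample Gaussian covariance of the
#' constrained estimator is `sigma2 * Q (Z'Z)^{-1} Q'`, which is singular
#' (rank P - m) by construction since the estimator lives on the constraint
#' surface.
#'
#' @param design An `"abc_design"` from [constrained_design()].
#' @param y Optional outcome vector; defaults to the outcome stored in the
#'   design.
#' @param conf_level Confidence level for intervals (default 0.95).
#' @return An object of class `"abc_fit"`: coefficients `theta_hat` (named),
#'   reduced coefficients `zeta_hat`, `sigma2_hat`, residual `df`, `vcov`,
#'   `se`, `t_stat`, `p_value`, `ci_lower`, `ci_upper`, `fitted`,
#'   `residuals`, plus the design metadata.
#' @examples
#' d <- data.frame(y = rnorm(40), x = rnorm(40), g = rep(c("A", "B"), 20))
#' sp <- model_spec("y", "x", list(g = NULL), modifiers = "all")
#' fit <- fit_ols(constrained_design(sp, d))
#' coef(fit)
#' @export
fit_ols <- function(design, y = NULL, conf_level = 0.95) {
  stopifnot(inherits(design, "abc_design"))
  if (is.null(design$Q))
    stop("design has no reparametrization; use constrained_design()")
  if (identical(design$spec$scheme, "OVER"))
    stop("the overparametrized scheme has no unique OLS solution; ",
         "use fit_ridge() or fit_lasso_path()")
  if (is.null(y)) y <- design$y
  Z <- design$Z
  n <- nrow(Z); k <- ncol(Z)
  if (n <= k) stop("need n > P - m observations for OLS (n = ", n,
                   ", free parameters = ", k, ")")
  dec <- qr(Z)
  if (dec$rank < k) {
    bad <- colnames(design$X)[setdiff(seq_len(ncol(design$X)),
                                      integer(0))]
    # identify offending original columns by checking X's rank pattern
    xdec <- qr(design$X)
    expect_rank <- ncol(design$X) - nrow(design$C)
    drop_idx <- if (xdec$rank < expect_rank)
      xdec$pivot[(xdec$rank + 1L):ncol(design$X)] else integer(0)
    stop("reduced design is rank-deficient (rank ", dec$rank, " < ", k,
         "); collinear or empty-level columns",
         if (length(drop_idx)) paste0(": ",
           paste(colnames(design$X)[drop_idx], collapse = ", ")))
  }
  zeta_hat <- qr.coef(dec, y)
  fitted <- drop(Z %*% zeta_hat)
  resid <- y - fitted
  df <- n - k
  rss <- sum(resid^2)
  sigma2_hat <- rss / df
  ZtZinv <- chol2inv(qr.R(dec))
  Q <- design$Q
  vcov <- sigma2_hat * Q %*% ZtZinv %*% t(Q)
  theta_hat <- drop(Q %*% zeta_hat)
  names(theta_hat) <- colnames(design$X)
  dimnames(vcov) <- list(names(theta_hat), names(theta_hat))
  se <- sqrt(pmax(diag(vcov), 0))
  tval <- ifelse(se > 0, theta_hat / se, NA_real_)
  pval <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  qt <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(
    list(theta_hat = theta_hat, zeta_hat = zeta_hat,
         sigma2_hat = sigma2_hat, df = df, vcov = vcov,
         se = se, t_stat = tval, p_value = pval,
         ci_lower = theta_hat - qt * se, ci_upper = theta_hat + qt * se,
         fitted = fitted, residuals = resid,
         conf_level = conf_level,
         labels = design$labels, spec = design$spec,
         proportions = design$proportions, n = n),
    class = "abc_fit"
  )
}

#' @export
coef.abc_fit <- function(object, ...) object$theta_hat

#' @export
vcov.abc_fit <- function(object, ...) object$vcov

#' @export
print.abc_fit <- function(x, ...) {
  cat("Constrained OLS fit (", x$spec$scheme, "): n = ", x$n,
      ", residual df = ", x$df, ", sigma^2 = ",
      format(x$sigma2_hat, digits = 4), "\n", sep = "")
  print(coefficient_inference(x), ...)
  invisible(x)
}

#' Per-coefficient inference table
#'
#' Standard errors from the constrained covariance, t statistics against
#' zero, two-sided p-values, and confidence intervals on the t distribution
#' with the fit's residual degrees of freedom.  Every categorical level is
#' reported - there is no omitted reference row.
#'
#' @param fit An `"abc_fit"`.
#' @param conf_level Confidence level (defaults to the one used at fit
#'   time).
#' @param p_adjust Multiple-testing adjustment method passed to
#'   [stats::p.adjust()]; `"none"` (the default) reports raw per-coefficient
#'   p-values.
#' @return A data.frame with one row per coefficient: `term`, `role`,
#'   `estimate`, `se`, `t_stat`, `p_value`, `ci_lower`, `ci_upper`.
#' @export
coefficient_inference <- function(fit, conf_level = NULL, p_adjust = "none") {
  stopifnot(inherits(fit, "abc_fit"))
  if (fit$df <= 0L) stop("no residual degrees of freedom for inference")
  if (is.null(conf_level)) conf_level <- fit$conf_level
  qt <- stats::qt(1 - (1 - conf_level) / 2, fit$df)
  p <- fit$p_value
  if (!identical(p_adjust, "none")) p <- stats::p.adjust(p, method = p_adjust)
  data.frame(
    term = names(fit$theta_hat), role = fit$labels$role,
    estimate = unname(fit$theta_hat), se = unname(fit$se),
    t_stat = unname(fit$t_stat), p_value = unname(p),
    ci_lower = unname(fit$theta_hat - qt * fit$se),
    ci_upper = unname(fit$theta_hat + qt * fit$se),
    stringsAsFactors = FALSE
  )
}
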