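#' Standardizing penalty weights
#'
#' The weighted penalty `sum_j omega_j |theta_j|^delta` uses the
#' population-style sample standard deviation of each design column as its
#' weight (`omega = 1` for the intercept column).  This standardizes the
#' penalty across covariates, and - crucial under abundance-based
#' constraints - avoids overpenalizing the coefficients of low-abundance
#' groups, whose indicator columns have small standard deviations but whose
#' coefficients are correspondingly larger.
#'
#' @param design An `"abc_design"`.
#' @return Named numeric vector `omega` of length P.
#' @export
penalty_weights <- function(design) {
  stopifnot(inherits(design, "abc_design"))
  X <- design$X
  ctr <- colMeans(X)
  omega <- sqrt(colMeans(sweep(X, 2, ctr)^2))
  intercept <- design$labels$role == "intercept"
  omega[intercept] <- 1
  if (any(omega <= 0))
    stop("zero-variance non-intercept column(s): ",
         paste(colnames(X)[omega <= 0], collapse = ", "))
  names(omega) <- colnames(X)
  omega
}

#' Constrained weighted ridge regression
#'
#' Closed-form solution of the constrained penalized least squares problem
#' with `delta = 2`:
#' `theta(lambda) = Q (Z'Z + lambda D'D)^{-1} Z'y`, where
#' `D = diag(omega^{1/2}) Q`, so the penalty `lambda * sum omega_j theta_j^2`
#' acts on the original coefficients while the optimization runs in the
#' reduced (unconstrained) coordinates.  The constraints are satisfied
#' exactly for every `lambda`.
#'
#' @param design An `"abc_design"`.
#' @param y Outcome vector (defaults to the design's).
#' @param lambda Non-negative penalty.
#' @param omega Penalty weights; defaults to [penalty_weights()].
#' @return Named coefficient vector of length P.
#' @export
fit_ridge <- function(design, y = NULL, lambda, omega = NULL) {
  stopifnot(inherits(design, "abc_design"), lambda >= 0)
  if (is.null(design$Q))
    stop("design has no reparametrization; use constrained_design()")
  if (is.null(y)) y <- design$y
  if (is.null(omega)) omega <- penalty_weights(design)
  Z <- design$Z; Q <- design$Q
  A <- crossprod(Z) + lambda * t(Q) %*% (omega * Q)
  b <- crossprod(Z, y)
  zeta <- tryCatch(solve(A, b), error = function(e)
    stop("singular ridge system (lambda = ", lambda,
         "): rank-deficient design", call. = FALSE))
  theta <- drop(Q %*% zeta)
  names(theta) <- colnames(design$X)
  theta
}

# Soft-threshold operator.
soft <- function(x, k) sign(x) * pmax(abs(x) - k, 0)

# Largest penalty for which theta = 0 is optimal for the constrained
# weighted lasso: the zero subgradient condition is implied by
# lambda >= 2 max_j |x_j' y| / omega_j.
lasso_lambda_max <- function(design, y = NULL, omega = NULL) {
  if (is.null(y)) y <- design$y
  if (is.null(omega)) omega <- penalty_weights(design)
  max(2 * abs(crossprod(design$X, y)) / omega)
}

# Default log-spaced grid from lambda_max down to floor_frac * lambda_max.
lasso_lambda_grid <- function(design, y = NULL, omega = NULL,
                              n_lambda = 100, floor_frac = 1e-4) {
  lmax <- lasso_lambda_max(design, y, omega)
  g <- exp(seq(log(lmax), log(floor_frac * lmax), length.out = n_lambda))
  g[1] <- lmax                           # guard the exact-zero endpoint
  g
}

# ADMM solve of the generalized lasso in reduced coordinates:
#   min_zeta ||y - Z zeta||^2 + lambda ||diag(omega) Q zeta||_1
# Scaled ADMM with splitting u = A zeta, A = diag(omega) Q.  Residual
# balancing adapts rho; the (2 Z'Z + rho A'A) factorization is reused
# until rho changes.
admm_genlasso <- function(Z, Q, y, omega, lambda,
                          zeta0 = NULL, u0 = NULL, w0 = NULL,
                          eps_abs = 1e-8, eps_rel = 1e-6, max_iter = 50000L) {
  A <- omega * Q                      # P x k
  k <- ncol(Z); P <- nrow(A)
  ZtZ2 <- 2 * crossprod(Z)
  Zty2 <- 2 * crossprod(Z, y)
  AtA <- crossprod(A)
  rho <- max(lambda, 1e-3)
  ch <- chol(ZtZ2 + rho * AtA)
  zeta <- if (is.null(zeta0)) rep(0, k) else zeta0
  u <- if (is.null(u0)) drop(A %*% zeta) else u0
  w <- if (is.null(w0)) rep(0, P) else w0
  for (it in seq_len(max_iter)) {
    zeta <- backsolve(ch, forwardsolve(t(ch), Zty2 + rho * crossprod(A, u - w)))
    Az <- drop(A %*% zeta)
    u_prev <- u
    u <- soft(Az + w, lambda / rho)
    w <- w + Az - u
    r_pri <- sqrt(sum((Az - u)^2))
    r_dua <- rho * sqrt(sum((crossprod(A, u - u_prev))^2))
    eps_pri <- sqrt(P) * eps_abs + eps_rel * max(sqrt(sum(Az^2)), sqrt(sum(u^2)))
    eps_dua <- sqrt(k) * eps_abs + eps_rel * rho * sqrt(sum(crossprod(A, w)^2))
    if (r_pri <= eps_pri && r_dua <= eps_dua)
      return(list(zeta = drop(zeta), u = u, w = w, iter = it,
                  converged = TRUE, rho = rho))
    if (it %% 50L == 0L) {
      if (r_pri > 10 * r_dua) {
        rho <- rho * 2; w <- w / 2
        ch <- chol(ZtZ2 + rho * AtA)
      } else if (r_dua > 10 * r_pri) {
        rho <- rho / 2; w <- w * 2
        ch <- chol(ZtZ2 + rho * AtA)
      }
    }
  }
  list(zeta = drop(zeta), u = u, w = w, iter = max_iter,
       converged = FALSE, rho = rho)
}

# KKT polish of an ADMM lasso iterate: the splitting variable u carries
# exact zeros, so fix the zero pattern and active signs it implies and
# solve the resulting equality-constrained quadratic program exactly.
# Kept only when it does not worsen the objective and the active signs
# are self-consistent; otherwise the ADMM point is returned.
polish_lasso <- function(theta_admm, u, design, y, lambda, omega) {
  zero <- u == 0
  if (!any(zero) || all(zero)) {
    if (all(zero)) theta_admm[] <- 0
    return(theta_admm)
  }
  X <- design$X; C <- design$C
  P <- ncol(X)
  s <- sign(u)
  E <- diag(P)[zero, , drop = FALSE]
  Ct <- rbind(C, E)
  # drop redundant rows (a constraint row may lie in the span of E)
  qrc <- qr(t(Ct))
  if (qrc$rank < nrow(Ct)) Ct <- Ct[qrc$pivot[seq_len(qrc$rank)], , drop = FALSE]
  m2 <- nrow(Ct)
  K <- rbind(cbind(2 * crossprod(X), t(Ct)),
             cbind(Ct, matrix(0, m2, m2)))
  rhs <- c(2 * crossprod(X, y) - lambda * omega * s, rep(0, m2))
  th <- tryCatch(drop(solve(K, rhs))[seq_len(P)],
                 error = function(e) NULL)
  if (is.null(th)) return(theta_admm)
  sign_ok <- all(th[!zero] * s[!zero] >= -1e-10)
  obj <- function(t) sum((y - X %*% t)^2) + lambda * sum(omega * abs(t))
  if (sign_ok && obj(th) <= obj(theta_admm) + 1e-9 * (1 + abs(obj(theta_admm))))
    th else theta_admm
}

#' Constrained weighted lasso path
#'
#' Solves, for each penalty on a decreasing grid, the constrained lasso
#' `min ||y - X theta||^2 + lambda sum_j omega_j |theta_j|` subject to
#' `C theta = 0`.  In the reduced coordinates `theta = Q zeta` this is a
#' generalized lasso, solved by scaled ADMM with warm starts down the grid.
#' When the zero-solution optimality certificate holds
#' (`lambda >= 2 max_j |x_j'y| / omega_j`), exact zeros are returned
#' without iteration.
#'
#' @param design An `"abc_design"` (any scheme; `OVER` uses the identity
#'   basis).
#' @param y Outcome vector (defaults to the design's).
#' @param lambda_grid Strictly decreasing positive penalties; defaults to
#'   100 log-spaced values from the full-shrinkage bound down to `1e-4`
#'   times it.
#' @param omega Penalty weights; defaults to [penalty_weights()].
#' @param eps_abs,eps_rel,max_iter ADMM tolerances and iteration cap.
#' @return An object of class `"abc_penalty_path"`: `lambda_grid`,
#'   `theta` (P x n_lambda matrix, each column satisfying the constraints),
#'   `iterations`, `converged`.
#' @export
fit_lasso_path <- function(design, y = NULL, lambda_grid = NULL,
                           omega = NULL, eps_abs = 1e-8, eps_rel = 1e-6,
                           max_iter = 50000L) {
  stopifnot(inherits(design, "abc_design"))
  if (is.null(design$Q))
    stop("design has no reparametrization; use constrained_design()")
  if (is.null(y)) y <- design$y
  if (is.null(omega)) omega <- penalty_weights(design)
  if (is.null(lambda_grid)) lambda_grid <- lasso_lambda_grid(design, y, omega)
  if (any(diff(lambda_grid) >= 0)) stop("lambda_grid must be strictly decreasing")
  if (any(lambda_grid <= 0)) stop("lambda_grid must be positive")
  Z <- design$Z; Q <- design$Q
  lmax <- lasso_lambda_max(design, y, omega)
  P <- ncol(design$X); nl <- length(lambda_grid)
  theta <- matrix(0, P, nl, dimnames = list(colnames(design$X), NULL))
  iters <- integer(nl); conv <- logical(nl)
  state <- NULL
  for (i in seq_len(nl)) {
    lam <- lambda_grid[i]
    if (lam >= lmax * (1 - 1e-12)) {        # exact full shrinkage
      iters[i] <- 0L; conv[i] <- TRUE
      next
    }
    res <- admm_genlasso(Z, Q, y, omega, lam,
                         zeta0 = state$zeta, u0 = state$u, w0 = state$w,
                         eps_abs = eps_abs, eps_rel = eps_rel,
                         max_iter = max_iter)
    if (!res$converged)
      stop("ADMM failed to converge at lambda = ", format(lam),
           " after ", max_iter, " iterations")
    th_admm <- drop(Q %*% res$zeta)
    theta[, i] <- polish_lasso(th_admm, res$u, design, y, lam, omega)
    iters[i] <- res$iter; conv[i] <- TRUE
    state <- res
  }
  structure(list(lambda_grid = lambda_grid, theta = theta,
                 omega = omega, iterations = iters, converged = conv),
            class = "abc_penalty_path")
}

#' @export
print.abc_penalty_path <- function(x, ...) {
  cat("Penalty path:", length(x$lambda_grid), "lambda values,",
      nrow(x$theta), "coefficients\n")
  invisible(x)
}

#' Cross-validated penalty selection
#'
#' K-fold cross-validation of the constrained ridge (`delta = 2`) or lasso
#' (`delta = 1`) over a penalty grid, reporting the per-lambda mean held-out
#' squared prediction error and its standard error across folds, the
#' minimizing penalty, and the one-standard-error choice (the largest
#' penalty whose mean error is within one standard error of the minimum).
#' Folds are stratified by the first categorical variable; a fold whose
#' training part loses an entire level is redrawn once.
#'
#' @param design An `"abc_design"`.
#' @param y Outcome vector (defaults to the design's).
#' @param delta 1 (lasso) or 2 (ridge).
#' @param lambda_grid Decreasing positive penalties; a default grid is
#'   derived from the data when omitted.
#' @param K Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param omega Penalty weights; defaults to [penalty_weights()].
#' @return An object of class `"abc_cv"`: `lambda_grid`, `cv_mean`,
#'   `cv_se`, `lambda_min`, `lambda_1se`, `K`, `seed`, `delta`, `fold_id`,
#'   and the full-data `path` (coefficients at every lambda).
#' @export
cross_validate_path <- function(design, y = NULL, delta = 1,
                                lambda_grid = NULL, K = 10L, seed = 1L,
                                omega = NULL) {
  stopifnot(inherits(design, "abc_design"), delta %in% c(1, 2), K >= 2L)
  if (is.null(y)) y <- design$y
  n <- nrow(design$X)
  if (n < 2L * K) stop("need n >= 2K observations for ", K, "-fold CV")
  if (is.null(omega)) omega <- penalty_weights(design)
  if (is.null(lambda_grid))
    lambda_grid <- lasso_lambda_grid(design, y, omega)
  nl <- length(lambda_grid)

  strat <- if (length(design$spec$categoricals)) {
    as.character(
      # first categorical column as recorded in the indicator block
      apply(design$X[, design$labels$role == "level" &
                       design$labels$cat == names(design$spec$categoricals)[1],
                     drop = FALSE], 1L, which.max))
  } else rep("all", n)

  assign_folds <- function() {
    fold <- integer(n)
    for (s in unique(strat)) {
      idx <- sample(which(strat == s))
      fold[idx] <- rep_len(sample(K), length(idx))
    }
    fold
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  fold_id <- assign_folds()
  lvl_cols <- which(design$labels$role == "level")
  fold_ok <- function(fold) all(vapply(seq_len(K), function(k) {
    tr <- fold != k
    !any(colSums(design$X[tr, lvl_cols, drop = FALSE]) == 0)
  }, logical(1)))
  if (!fold_ok(fold_id)) {
    fold_id <- assign_folds()
    if (!fold_ok(fold_id))
      stop("cross-validation folds lose an entire categorical level; ",
           "reduce K or merge rare levels")
  }

  fit_grid <- function(rows) {
    sub <- design
    sub$X <- design$X[rows, , drop = FALSE]
    sub$Z <- design$Z[rows, , drop = FALSE]
    sub$y <- y[rows]
    if (delta == 2) {
      vapply(lambda_grid, function(l) fit_ridge(sub, lambda = l, omega = omega),
             numeric(ncol(design$X)))
    } else {
      fit_lasso_path(sub, lambda_grid = lambda_grid, omega = omega)$theta
    }
  }

  err <- matrix(NA_real_, K, nl)
  for (k in seq_len(K)) {
    tr <- fold_id != k
    th <- fit_grid(tr)
    pred <- design$X[!tr, , drop = FALSE] %*% th
    err[k, ] <- colMeans((y[!tr] - pred)^2)
  }
  cv_mean <- colMeans(err)
  cv_se <- apply(err, 2, stats::sd) / sqrt(K)
  i_min <- which.min(cv_mean)
  ok <- cv_mean <= cv_mean[i_min] + cv_se[i_min]
  lambda_1se <- max(lambda_grid[ok])
  full <- fit_grid(rep(TRUE, n))
  structure(list(lambda_grid = lambda_grid, cv_mean = cv_mean, cv_se = cv_se,
                 lambda_min = lambda_grid[i_min], lambda_1se = lambda_1se,
                 K = K, seed = seed, delta = delta, fold_id = fold_id,
                 theta = full),
            class = "abc_cv")
}

#' @export
print.abc_cv <- function(x, ...) {
  cat("Cross-validation (delta =", x$delta, ", K =", x$K, "):\n")
  cat("  lambda_min =", format(x$lambda_min, digits = 4),
      " lambda_1se =", format(x$lambda_1se, digits = 4), "\n")
  invisible(x)
}

#' Coefficients at a selected penalty
#'
#' @param cv An `"abc_cv"` object.
#' @param rule `"1se"` (default) or `"min"`.
#' @return Named coefficient vector at the selected penalty.
#' @export
selected_coefficients <- function(cv, rule = c("1se", "min")) {
  rule <- match.arg(rule)
  lam <- if (rule == "1se") cv$lambda_1se else cv$lambda_min
  cv$theta[, which.min(abs(cv$lambda_grid - lam))]
}
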