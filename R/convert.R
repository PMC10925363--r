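#' Construct a scheme-tagged coefficient set
#'
#' A coefficient set carries a fitted or published model's coefficients in
#' structured form: the intercept, the continuous main effects, one
#' coefficient per level of every categorical, and one per level of every
#' modifier pair - together with the identification scheme they satisfy and
#' the group proportions needed to move between schemes.  Reference-level
#' entries omitted from an RGE input are imputed as exact zeros.
#'
#' @param scheme `"ABC"`, `"RGE"`, or `"STZ"`.
#' @param alpha0 Intercept.
#' @param alpha Named numeric vector of continuous main effects (may be
#'   empty).
#' @param beta Named list: per categorical, a named numeric vector over its
#'   levels.
#' @param gamma Named list of named lists: `gamma[[cat]][[cont]]` is a
#'   named numeric vector over the levels of `cat` (omit pairs with no
#'   modifier).
#' @param proportions An `abc_proportions` object (or a named list of
#'   per-level weight vectors).
#' @param reference_levels Named character vector (required for RGE).
#' @param check Verify the scheme's defining constraints (default TRUE,
#'   tolerance `1e-6` to admit published, rounded tables).
#' @return An object of class `"abc_coefficients"`.
#' @export
coefficient_set <- function(scheme, alpha0, alpha = numeric(0),
                            beta = list(), gamma = list(),
                            proportions, reference_levels = NULL,
                            check = TRUE) {
  scheme <- match.arg(scheme, c("ABC", "RGE", "STZ"))
  if (!is.list(proportions)) stop("'proportions' must be a named list")
  for (cc in names(beta)) {
    lv <- names(proportions[[cc]])
    if (is.null(lv)) stop("proportions missing for categorical '", cc, "'")
    b <- beta[[cc]]
    missing_lv <- setdiff(lv, names(b))
    if (length(missing_lv)) {
      if (scheme != "RGE" || !all(missing_lv == reference_levels[[cc]]))
        stop("beta for '", cc, "' missing level(s): ",
             paste(missing_lv, collapse = ", "))
      b[missing_lv] <- 0
    }
    beta[[cc]] <- b[lv]
  }
  for (cc in names(gamma)) for (xx in names(gamma[[cc]])) {
    lv <- names(proportions[[cc]])
    g <- gamma[[cc]][[xx]]
    missing_lv <- setdiff(lv, names(g))
    if (length(missing_lv)) {
      if (scheme != "RGE" || !all(missing_lv == reference_levels[[cc]]))
        stop("gamma for ", xx, ":", cc, " missing level(s): ",
             paste(missing_lv, collapse = ", "))
      g[missing_lv] <- 0
    }
    gamma[[cc]][[xx]] <- g[lv]
  }
  obj <- structure(
    list(scheme = scheme, alpha0 = unname(alpha0), alpha = alpha,
         beta = beta, gamma = gamma, proportions = proportions,
         reference_levels = reference_levels),
    class = "abc_coefficients")
  if (check) {
    dev <- scheme_constraint_deviation(obj)
    if (dev > 1e-6)
      stop("coefficients violate the ", scheme,
           " constraints (max deviation ", format(dev), ")")
  }
  obj
}

# Maximum absolute deviation from the scheme's defining block constraints.
scheme_constraint_deviation <- function(cs) {
  dev <- 0
  blocks <- c(lapply(names(cs$beta), function(cc) list(cc, cs$beta[[cc]])),
              unlist(lapply(names(cs$gamma), function(cc)
                lapply(names(cs$gamma[[cc]]), function(xx)
                  list(cc, cs$gamma[[cc]][[xx]]))), recursive = FALSE))
  for (b in blocks) {
    cc <- b[[1]]; v <- b[[2]]
    d <- switch(cs$scheme,
      ABC = abs(sum(cs$proportions[[cc]][names(v)] * v)),
      STZ = abs(sum(v)),
      RGE = abs(v[[cs$reference_levels[[cc]]]]))
    dev <- max(dev, d)
  }
  dev
}

#' Parametrization-invariant per-group intercepts and slopes
#'
#' Every identification scheme describes the same fitted surface; the
#' scheme-free quantities are the per-group intercepts
#' `mu(0, r) = alpha0 + beta_r` and the group-specific slopes
#' `mu'_j(r) = alpha_j + gamma_{r,j}`.  Converting a coefficient set to any
#' scheme leaves these unchanged.
#'
#' @param coeffs An `"abc_coefficients"` object.
#' @return A list with `intercepts` (per categorical: named vector over
#'   levels of `alpha0 + beta_r`), `slopes` (per categorical, per modified
#'   covariate: named vector of `alpha_j + gamma_{r,j}`), and
#'   `unmodified_slopes` (the plain `alpha` for covariates with no
#'   modifier).
#' @export
canonical_effects <- function(coeffs) {
  stopifnot(inherits(coeffs, "abc_coefficients"))
  intercepts <- lapply(coeffs$beta, function(b) coeffs$alpha0 + b)
  slopes <- list()
  for (cc in names(coeffs$gamma)) {
    slopes[[cc]] <- list()
    for (xx in names(coeffs$gamma[[cc]]))
      slopes[[cc]][[xx]] <- coeffs$alpha[[xx]] + coeffs$gamma[[cc]][[xx]]
  }
  modified <- unique(unlist(lapply(coeffs$gamma, names)))
  unmod <- coeffs$alpha[setdiff(names(coeffs$alpha), modified)]
  list(intercepts = intercepts, slopes = slopes, unmodified_slopes = unmod)
}

#' Convert a coefficient set between identification schemes
#'
#' Computes the scheme-invariant per-group intercepts and slopes and
#' re-centers them per the target scheme: ABCs take proportion-weighted
#' block means as the global effects, sum-to-zero takes unweighted means,
#' and reference-group encoding subtracts the reference group's values.
#' The conversion is an exact linear map on the coefficients; it never
#' touches data.  (With several categorical variables the intercept is
#' re-centered sequentially across blocks, matching the marginal form of
#' the constraints.)
#'
#' @param coeffs An `"abc_coefficients"` object.
#' @param target `"ABC"`, `"RGE"`, or `"STZ"`.
#' @param proportions Proportions used for the ABC target; defaults to
#'   those stored in `coeffs`.
#' @param reference_levels Required when `target = "RGE"`.
#' @return An `"abc_coefficients"` object satisfying the target scheme's
#'   constraints exactly.
#' @examples
#' # published RGE output for an RI-on-reading-scores model, converted to ABCs
#' cs <- coefficient_set(
#'   scheme = "RGE", alpha0 = 0.267, alpha = c(RI = -0.013),
#'   beta = list(race = c(NHW = 0, NHB = -0.670, Hisp = -0.191)),
#'   gamma = list(race = list(RI = c(NHW = 0, NHB = -0.057, Hisp = 0.034))),
#'   proportions = list(race = c(NHW = 0.58, NHB = 0.36, Hisp = 0.06)),
#'   reference_levels = c(race = "NHW"))
#' convert_scheme(cs, "ABC")
#' @export
convert_scheme <- function(coeffs, target, proportions = NULL,
                           reference_levels = NULL) {
  stopifnot(inherits(coeffs, "abc_coefficients"))
  target <- match.arg(target, c("ABC", "RGE", "STZ"))
  if (is.null(proportions)) proportions <- coeffs$proportions
  if (target == "RGE") {
    if (is.null(reference_levels)) reference_levels <- coeffs$reference_levels
    if (is.null(reference_levels))
      stop("RGE target requires reference levels")
  }
  center <- function(v, cc) switch(target,
    ABC = sum(proportions[[cc]][names(v)] * v),
    STZ = mean(v),
    RGE = v[[reference_levels[[cc]]]])
  # shifting each block's center into the intercept (or main effect)
  # preserves the per-group intercepts mu(0, r) and slopes mu'_j(r)
  alpha0 <- coeffs$alpha0
  beta <- coeffs$beta
  for (cc in names(beta)) {
    shift <- center(beta[[cc]], cc)
    beta[[cc]] <- beta[[cc]] - shift
    alpha0 <- alpha0 + shift
  }
  alpha <- coeffs$alpha
  gamma <- coeffs$gamma
  for (cc in names(gamma)) for (xx in names(gamma[[cc]])) {
    shift <- center(gamma[[cc]][[xx]], cc)
    gamma[[cc]][[xx]] <- gamma[[cc]][[xx]] - shift
    alpha[[xx]] <- alpha[[xx]] + shift
  }
  coefficient_set(target, alpha0, alpha, beta, gamma,
                  proportions = proportions,
                  reference_levels = reference_levels, check = FALSE)
}

#' Extract a coefficient set from a constrained OLS fit
#'
#' @param fit An `"abc_fit"`.
#' @return An `"abc_coefficients"` object tagged with the fit's scheme.
#' @export
as_coefficient_set <- function(fit) {
  stopifnot(inherits(fit, "abc_fit"))
  lab <- fit$labels; th <- fit$theta_hat
  alpha0 <- unname(th[lab$role == "intercept"])
  alpha <- th[lab$role == "main"]
  names(alpha) <- lab$cont[lab$role == "main"]
  props <- fit$proportions
  if (is.null(props)) {
    # reconstruct level sets with unit weights for non-ABC fits (the
    # weights are only needed for an ABC conversion target)
    props <- lapply(split(lab$level[lab$role == "level"],
                          lab$cat[lab$role == "level"]), function(lv) {
      p <- rep(NA_real_, length(lv)); names(p) <- lv; p
    })
  }
  beta <- list(); gamma <- list()
  for (cc in unique(lab$cat[lab$role == "level"])) {
    sel <- lab$role == "level" & lab$cat == cc
    b <- th[sel]; names(b) <- lab$level[sel]
    beta[[cc]] <- b
  }
  ints <- lab$role == "interaction"
  if (any(ints)) {
    for (cc in unique(lab$cat[ints])) {
      gamma[[cc]] <- list()
      for (xx in unique(lab$cont[ints & lab$cat == cc])) {
        sel <- ints & lab$cat == cc & lab$cont == xx
        g <- th[sel]; names(g) <- lab$level[sel]
        gamma[[cc]][[xx]] <- g
      }
    }
  }
  coefficient_set(fit$spec$scheme, alpha0, alpha, beta, gamma,
                  proportions = props,
                  reference_levels = fit$spec$reference_levels,
                  check = FALSE)
}

#' Render an equitable coefficient table
#'
#' Lists the intercept, every continuous main effect, every level of every
#' categorical (no omitted reference), and every interaction level, grouped
#' by variable.  For a reference-group-encoded set the reference level is
#' named explicitly in a header note and its constrained-to-zero rows are
#' shown rather than hidden.  Rendered estimates are rounded to 3 decimals;
#' the underlying objects keep full precision.
#'
#' @param x An `"abc_fit"` or `"abc_coefficients"`.
#' @param format `"tsv"` or `"markdown"`.
#' @param digits Decimal places for rendering (default 3).
#' @return A character vector of table lines (invisibly printed with
#'   `cat`-style newlines when auto-printed).
#' @export
equitable_report <- function(x, format = c("tsv", "markdown"), digits = 3) {
  format <- match.arg(format)
  fit <- NULL
  if (inherits(x, "abc_fit")) { fit <- x; cs <- as_coefficient_set(x) }
  else if (inherits(x, "abc_coefficients")) cs <- x
  else stop("x must be an abc_fit or abc_coefficients object")
  fmt <- function(v) formatC(round(v, digits), format = "f", digits = digits)
  inf <- if (!is.null(fit)) coefficient_inference(fit) else NULL
  lookup <- function(term) {
    if (is.null(inf)) return(c(NA, NA))
    i <- match(term, inf$term)
    c(inf$se[i], inf$p_value[i])
  }
  sep <- if (format == "tsv") "\t" else " | "
  hdr <- paste(c("Variable", "Estimate",
                 if (!is.null(inf)) c("SE", "p-value")), collapse = sep)
  lines <- character(0)
  if (cs$scheme == "RGE")
    lines <- c(lines, paste0("# reference group: ",
                             paste(sprintf("%s=%s", names(cs$reference_levels),
                                           cs$reference_levels),
                                   collapse = ", ")))
  lines <- c(lines, hdr)
  if (format == "markdown")
    lines <- c(lines, paste(rep("---", length(strsplit(hdr, " \\| ")[[1]])),
                            collapse = " | "))
  row <- function(name, est, term = NULL) {
    extra <- if (!is.null(inf)) {
      sp <- lookup(term)
      paste0(sep, fmt(sp[1]), sep, fmt(sp[2]))
    } else ""
    paste0(name, sep, fmt(est), extra)
  }
  lines <- c(lines, row("(Intercept)", cs$alpha0, "(Intercept)"))
  for (xx in names(cs$alpha))
    lines <- c(lines, row(xx, cs$alpha[[xx]], xx))
  for (cc in names(cs$beta)) {
    lines <- c(lines, paste0(if (format == "markdown") "**", cc,
                             if (format == "markdown") "**"))
    for (r in names(cs$beta[[cc]]))
      lines <- c(lines, row(paste0("  ", r), cs$beta[[cc]][[r]],
                            paste0(cc, "=", r)))
  }
  for (cc in names(cs$gamma)) for (xx in names(cs$gamma[[cc]])) {
    lines <- c(lines, paste0(if (format == "markdown") "**",
                             xx, " x ", cc,
                             if (format == "markdown") "**"))
    for (r in names(cs$gamma[[cc]][[xx]]))
      lines <- c(lines, row(paste0("  ", xx, ":", r),
                            cs$gamma[[cc]][[xx]][[r]],
                            paste0(xx, ":", cc, "=", r)))
  }
  structure(lines, class = "abc_report")
}

#' @export
print.abc_report <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}

#' @export
print.abc_coefficients <- function(x, ...) {
  cat("Coefficient set (", x$scheme, ")\n", sep = "")
  print(equitable_report(x))
  invisible(x)
}
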