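# Per-replicate seeds derived from a master seed so replicate k is
# invariant to the total replicate count.  Kept below 2^31.
replicate_seed <- function(master_seed, k) {
  as.integer((as.numeric(master_seed) * 48271 + k * 16807) %% 2147483647L) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Configuration of the misspecified-benchmark design
#'
#' The benchmark generates from a Gaussian main-only model with `p = 10`
#' continuous covariates and one 4-level categorical variable, then fits
#' the (misspecified) modifier-including model.  Six covariates are
#' independent standard normal; four (`X4, X5, X9, X10`) have group-mean
#' `r` (the group index) and unit variance.  True coefficients: intercept
#' 1, `alpha_1..5 = 1` (signal), `alpha_6..10 = 0` (noise), categorical
#' coefficients `beta = (0, 1, 0, -1)` - which satisfy both the
#' reference-group constraint (`beta_1 = 0`) and the abundance constraint
#' under the generating proportions.  The noise variance is set to the
#' analytic population variance of the signal, giving a signal-to-noise
#' ratio of one.
#'
#' @param n Sample size (the reference design uses 250 and 10000).
#' @param pi Group proportions; `"symmetric"` = (0.15, 0.35, 0.15, 0.35),
#'   `"uniform"` = (0.25, 0.25, 0.25, 0.25), or a length-4 numeric vector
#'   summing to 1.
#' @param n_reps Number of replicate datasets.
#' @param seed Master seed.
#' @param snr_definition `"population"` (default: analytic signal variance)
#'   or `"empirical"` (per-dataset sample variance of the signal).
#' @return A list of class `"abc_benchmark_config"`.
#' @export
benchmark_config <- function(n = 250, pi = "symmetric", n_reps = 500,
                             seed = 1L, snr_definition = "population") {
  if (identical(pi, "symmetric")) pi <- c(0.15, 0.35, 0.15, 0.35)
  if (identical(pi, "uniform")) pi <- c(0.25, 0.25, 0.25, 0.25)
  stopifnot(length(pi) == 4, abs(sum(pi) - 1) < 1e-8, all(pi > 0))
  snr_definition <- match.arg(snr_definition, c("population", "empirical"))
  p <- 10L
  alpha <- c(rep(1, 5), rep(0, 5))
  beta <- c(0, 1, 0, -1)
  group_dep <- c(4L, 5L, 9L, 10L)          # covariates with group-mean r
  stopifnot(abs(sum(pi * beta)) < 1e-12, beta[1] == 0)
  # analytic population variance of the signal  sum_j alpha_j X_j + beta_R:
  # independent part + variance of the group-dependent conditional mean
  dep_sig <- intersect(group_dep, which(alpha != 0))
  indep_sig <- setdiff(which(alpha != 0), group_dep)
  r_idx <- 1:4
  cond_mean <- vapply(r_idx, function(r)
    sum(alpha[dep_sig]) * r + beta[r], numeric(1))
  signal_var <- sum(alpha[indep_sig]^2) + length(dep_sig) +
    sum(pi * cond_mean^2) - sum(pi * cond_mean)^2
  structure(list(n = n, p = p, pi = pi, alpha0 = 1, alpha = alpha,
                 beta = beta, group_dep = group_dep,
                 signal_var = signal_var, sigma2 = signal_var,
                 n_reps = n_reps, seed = as.integer(seed),
                 snr_definition = snr_definition,
                 min_per_level = p + 1L, max_redraws = 1000L),
            class = "abc_benchmark_config")
}

#' Generate one benchmark replicate dataset
#'
#' Draws the categorical variable from the configured proportions, the ten
#' continuous covariates from the group-dependent Gaussian design, and the
#' outcome from the main-only truth plus Gaussian noise at
#' signal-to-noise ratio one.  A dataset in which any level has fewer than
#' `p + 1` observations is redrawn in full (bounded retries) - the minimum
#' needed to estimate every interaction block by OLS.
#'
#' @param config An `"abc_benchmark_config"`.
#' @param replicate Replicate index (seeds an independent substream).
#' @return A data.frame with columns `y`, `x1..x10`, `g` (levels
#'   `"1".."4"`).
#' @export
generate_benchmark_dataset <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "abc_benchmark_config"))
  with_seed(replicate_seed(config$seed, replicate), {
    for (attempt in seq_len(config$max_redraws)) {
      r <- sample.int(4L, config$n, replace = TRUE, prob = config$pi)
      if (min(tabulate(r, 4L)) >= config$min_per_level) break
      if (attempt == config$max_redraws)
        stop("failed to draw >= ", config$min_per_level,
             " observations per level in ", config$max_redraws, " attempts")
    }
    X <- matrix(stats::rnorm(config$n * config$p), config$n, config$p)
    for (j in config$group_dep) X[, j] <- X[, j] + r
    signal <- config$alpha0 + drop(X %*% config$alpha) + config$beta[r]
    sigma2 <- if (config$snr_definition == "empirical")
      stats::var(signal) else config$sigma2
    y <- signal + stats::rnorm(config$n, sd = sqrt(sigma2))
    d <- as.data.frame(X)
    names(d) <- paste0("x", seq_len(config$p))
    d$g <- as.character(r)
    d$y <- y
    d
  })
}

# Model spec for the benchmark's (misspecified) modifier-including fit.
benchmark_spec <- function(config, scheme, reference = "1") {
  model_spec(
    outcome = "y", continuous = paste0("x", seq_len(config$p)),
    categoricals = list(g = c("1", "2", "3", "4")),
    modifiers = "all", scheme = scheme,
    reference_levels = if (scheme == "RGE") c(g = reference))
}

# True coefficient vector in the layout of the modified-model design.
benchmark_truth <- function(config, labels) {
  th <- numeric(nrow(labels))
  th[labels$role == "intercept"] <- config$alpha0
  mains <- which(labels$role == "main")
  th[mains] <- config$alpha[match(labels$cont[mains],
                                  paste0("x", seq_len(config$p)))]
  lvls <- which(labels$role == "level")
  th[lvls] <- config$beta[as.integer(labels$level[lvls])]
  th                                        # all gamma are 0 in the truth
}

#' Run the scheme-by-estimator benchmark
#'
#' For each replicate, fits the modifier-including model under the
#' requested schemes and estimators and records root-mean-squared errors
#' against the known truth for (a) the regression coefficients, (b) the
#' group-specific slopes `alpha_j + gamma_{r,j}`, and (c) the model
#' expectations `mu(x, r)` on the observed design.  Ridge and lasso
#' penalties are selected per replicate by cross-validation with the
#' one-standard-error rule.  The overparametrized scheme is only valid for
#' penalized estimators.
#'
#' @param config An `"abc_benchmark_config"`.
#' @param schemes Character subset of `c("ABC", "RGE", "OVER")`.
#' @param estimators Character subset of `c("ols", "ridge", "lasso")`.
#' @param K Cross-validation folds for the penalized estimators.
#' @param n_lambda Penalty-grid size.
#' @return A list of class `"abc_benchmark_result"`: `per_replicate`
#'   (long data.frame: `replicate`, `scheme`, `estimator`, `rmse_coef`,
#'   `rmse_slopes`, `rmse_mu`), `summary` (medians by scheme/estimator),
#'   and per-replicate OLS fitted/slope cross-scheme agreement when both
#'   ABC and RGE are run with OLS.
#' @export
run_estimator_benchmark <- function(config,
                                    schemes = c("ABC", "RGE"),
                                    estimators = c("ols", "ridge", "lasso"),
                                    K = 5L, n_lambda = 50L) {
  stopifnot(inherits(config, "abc_benchmark_config"))
  schemes <- match.arg(schemes, c("ABC", "RGE", "OVER"), several.ok = TRUE)
  estimators <- match.arg(estimators, c("ols", "ridge", "lasso"),
                          several.ok = TRUE)
  if ("OVER" %in% schemes && "ols" %in% estimators && length(estimators) == 1L)
    stop("the overparametrized scheme cannot be estimated by OLS")
  rows <- list(); agree <- list()
  n_fail <- 0L
  for (k in seq_len(config$n_reps)) {
    d <- generate_benchmark_dataset(config, k)
    fits_ols <- list()
    for (sch in schemes) {
      des <- constrained_design(benchmark_spec(config, sch), d)
      truth <- benchmark_truth(config, des$labels)
      mu_true <- drop(des$X %*% truth)
      record <- function(est, theta) {
        sl_hat <- slope_table(theta, des$labels)
        sl_true <- slope_table(truth, des$labels)
        rows[[length(rows) + 1L]] <<- data.frame(
          replicate = k, scheme = sch, estimator = est,
          rmse_coef = sqrt(mean((theta - truth)^2)),
          rmse_slopes = sqrt(mean((sl_hat - sl_true)^2)),
          rmse_mu = sqrt(mean((drop(des$X %*% theta) - mu_true)^2)),
          stringsAsFactors = FALSE)
      }
      omega <- penalty_weights(des)
      for (est in estimators) {
        if (est == "ols") {
          if (sch == "OVER") next
          fit <- tryCatch(fit_ols(des), error = function(e) NULL)
          if (is.null(fit)) { n_fail <- n_fail + 1L; next }
          fits_ols[[sch]] <- fit
          record("ols", unname(fit$theta_hat))
        } else {
          grid <- lasso_lambda_grid(des, omega = omega, n_lambda = n_lambda)
          cv <- tryCatch(
            cross_validate_path(des, delta = if (est == "ridge") 2 else 1,
                                lambda_grid = grid, K = K,
                                seed = replicate_seed(config$seed, k) %% 100000L,
                                omega = omega),
            error = function(e) NULL)
          if (is.null(cv)) { n_fail <- n_fail + 1L; next }
          record(est, unname(selected_coefficients(cv, "1se")))
        }
      }
    }
    if (!is.null(fits_ols$ABC) && !is.null(fits_ols$RGE)) {
      agree[[length(agree) + 1L]] <- data.frame(
        replicate = k,
        max_fitted_diff = max(abs(fits_ols$ABC$fitted - fits_ols$RGE$fitted)),
        max_slope_diff = max(abs(
          slope_table(unname(fits_ols$ABC$theta_hat), fits_ols$ABC$labels) -
          slope_table(unname(fits_ols$RGE$theta_hat), fits_ols$RGE$labels))))
    }
  }
  per_rep <- do.call(rbind, rows)
  if (n_fail > 0.05 * config$n_reps * length(schemes) * length(estimators))
    stop("more than 5% of benchmark fits failed (", n_fail, " failures)")
  summ <- stats::aggregate(
    cbind(rmse_coef, rmse_slopes, rmse_mu) ~ scheme + estimator,
    data = per_rep, FUN = stats::median)
  structure(list(per_replicate = per_rep, summary = summ,
                 ols_agreement = if (length(agree)) do.call(rbind, agree),
                 n_failures = n_fail, config = config),
            class = "abc_benchmark_result")
}

# All group-specific slopes alpha_j + gamma_{r,j} implied by a coefficient
# vector in design layout (one entry per interaction column).
slope_table <- function(theta, labels) {
  ints <- which(labels$role == "interaction")
  main_idx <- vapply(labels$cont[ints], function(xx)
    which(labels$role == "main" & labels$cont == xx)[1], integer(1))
  theta[main_idx] + theta[ints]
}

#' Configuration of the estimation-invariance experiment
#'
#' Generates a categorical variable over groups A-D with probabilities
#' (0.55, 0.20, 0.10, 0.15) and a continuous covariate whose distribution
#' depends on the group: `A: 5 + N(0,1)`, `B: sqrt(12) U(0,1)`,
#' `C: 5 + t4 / sqrt(2)`, `D: Gamma(1,1)` - each with population variance
#' one (the t4 draw is scaled by `1/sqrt(2)` to meet the stated unit
#' variance; set `scale_t4 = FALSE` for the raw t4).  The outcome mean is
#' `1 + x + gamma x 1(r = A) - gamma x 1(r = B)` with t4-distributed
#' errors; `gamma` scales the modifier relative to the unit main effect.
#'
#' @param n Sample size (reference design: 100 and 500).
#' @param gamma Modifier strength (reference design: 0, 0.5, 1.5).
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param scale_t4 Scale the group-C t4 draws to unit variance (default
#'   TRUE).
#' @return A list of class `"abc_invariance_config"`.
#' @export
invariance_config <- function(n = 500, gamma = 0.5, n_reps = 500,
                              seed = 1L, scale_t4 = TRUE) {
  structure(list(n = n, gamma = gamma, pi = c(A = 0.55, B = 0.20,
                                              C = 0.10, D = 0.15),
                 n_reps = n_reps, seed = as.integer(seed),
                 scale_t4 = isTRUE(scale_t4)),
            class = "abc_invariance_config")
}

#' Generate one invariance-experiment dataset
#'
#' @param config An `"abc_invariance_config"`.
#' @param replicate Replicate index.
#' @return A data.frame with columns `y`, `x`, `g`.
#' @export
generate_invariance_dataset <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "abc_invariance_config"))
  with_seed(replicate_seed(config$seed, replicate), {
    g <- sample(names(config$pi), config$n, replace = TRUE,
                prob = config$pi)
    n <- config$n
    x <- numeric(n)
    iA <- g == "A"; iB <- g == "B"; iC <- g == "C"; iD <- g == "D"
    x[iA] <- 5 + stats::rnorm(sum(iA))
    x[iB] <- sqrt(12) * stats::runif(sum(iB))
    x[iC] <- 5 + stats::rt(sum(iC), df = 4) /
      (if (config$scale_t4) sqrt(2) else 1)
    x[iD] <- stats::rgamma(sum(iD), shape = 1, rate = 1)
    mu <- 1 + x + config$gamma * x * iA - config$gamma * x * iB
    data.frame(y = mu + stats::rt(n, df = 4), x = x, g = g,
               stringsAsFactors = FALSE)
  })
}

#' Run the estimation-invariance experiment
#'
#' For each replicate and each identification scheme (ABC, RGE with
#' reference A, STZ), fits the main-only and the modifier-including model
#' and records the main-effect estimates from both.  Summarizes the median
#' absolute discrepancy `|alpha1_modified - alpha1_main_only|` per scheme.
#'
#' @param config An `"abc_invariance_config"`.
#' @param schemes Schemes to compare.
#' @param standardize_within_group Standardize `x` within each group
#'   (population-style) before fitting; this enforces the equal-variance
#'   condition exactly.
#' @return A list of class `"abc_invariance_result"`: `per_replicate`
#'   (`replicate`, `scheme`, `alpha1_main`, `alpha1_mod`, `abs_diff`) and
#'   `summary` (median absolute discrepancy per scheme).
#' @export
run_invariance_experiment <- function(config,
                                      schemes = c("ABC", "RGE", "STZ"),
                                      standardize_within_group = FALSE) {
  stopifnot(inherits(config, "abc_invariance_config"))
  rows <- list()
  for (k in seq_len(config$n_reps)) {
    d <- generate_invariance_dataset(config, k)
    if (standardize_within_group) {
      for (gg in unique(d$g)) {
        i <- d$g == gg
        m <- mean(d$x[i]); s <- sqrt(mean((d$x[i] - m)^2))
        d$x[i] <- (d$x[i] - m) / s
      }
    }
    for (sch in schemes) {
      spec <- model_spec("y", "x", list(g = c("A", "B", "C", "D")),
                         modifiers = "all", scheme = sch,
                         reference_levels = if (sch == "RGE") c(g = "A"))
      f_mod <- fit_ols(constrained_design(spec, d))
      f_main <- fit_ols(constrained_design(drop_modifiers(spec), d))
      a_mod <- unname(f_mod$theta_hat[f_mod$labels$role == "main"])
      a_main <- unname(f_main$theta_hat[f_main$labels$role == "main"])
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = k, scheme = sch, alpha1_main = a_main,
        alpha1_mod = a_mod, abs_diff = abs(a_mod - a_main),
        stringsAsFactors = FALSE)
    }
  }
  per_rep <- do.call(rbind, rows)
  summ <- stats::aggregate(abs_diff ~ scheme, data = per_rep,
                           FUN = stats::median)
  names(summ)[2] <- "median_abs_diff"
  structure(list(per_replicate = per_rep, summary = summ, config = config),
            class = "abc_invariance_result")
}
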