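test_that("noiseless constraint-satisfying truth is recovered exactly", {
  set.seed(3)
  n <- 40
  g <- rep(c("A", "B"), each = n / 2)
  x <- rnorm(n)
  y <- 1 + 2 * x + ifelse(g == "A", 0.5, -0.5)
  d <- data.frame(y = y, x = x, g = g)
  sp <- model_spec("y", "x", list(g = c("A", "B")), modifiers = "none",
                   scheme = "ABC")
  fit <- fit_ols(constrained_design(sp, d))
  expect_equal(unname(fit$theta_hat), c(1, 2, 0.5, -0.5), tolerance = 1e-10)
  # zero-residual case: sigma2 = 0 and all se = 0
  expect_equal(fit$sigma2_hat, 0, tolerance = 1e-20)
  expect_equal(unname(fit$se), rep(0, 4), tolerance = 1e-10)
})

test_that("constrained OLS matches the KKT linear-system oracle", {
  for (s in 1:5) {
    d <- sim_simple(n = 12, seed = s)
    for (scheme in c("ABC", "RGE", "STZ")) {
      des <- constrained_design(
        simple_spec(scheme), d,
        proportions = estimate_proportions(d, simple_spec(scheme)))
      fit <- fit_ols(des)
      oracle <- kkt_ols_oracle(des$X, d$y, des$C)
      expect_lt(max(abs(unname(fit$theta_hat) - oracle)), 1e-9)
    }
  }
})

test_that("fitted values are identical across ABC/RGE/STZ schemes", {
  d <- sim_simple(n = 45, seed = 11, gamma = c(1, -1, 0))
  fits <- lapply(c("ABC", "RGE", "STZ"), function(sch)
    fit_ols(constrained_design(simple_spec(sch), d)))
  proj <- colspace_projection(
    constrained_design(simple_spec("ABC"), d)$X, d$y)
  for (f in fits) {
    expect_lt(max(abs(f$fitted - fits[[1]]$fitted)), 1e-9)
    expect_lt(max(abs(f$fitted - proj)), 1e-9)
    expect_equal(f$fitted + f$residuals, d$y, tolerance = 1e-12)
  }
})

test_that("constraints and ABC averaging identities hold on random problems", {
  for (s in 1:6) {
    pr <- random_problem(s)
    des <- constrained_design(pr$spec, pr$data)
    fit <- fit_ols(des)
    expect_lt(max(abs(des$C %*% fit$theta_hat)), 1e-8)
    pihat <- des$proportions
    lab <- fit$labels
    for (cc in names(des$spec$categoricals)) {
      sel <- lab$role == "level" & lab$cat == cc
      expect_lt(abs(sum(pihat[[cc]][lab$level[sel]] * fit$theta_hat[sel])),
                1e-10)
    }
    for (m in des$spec$modifiers) {
      sel <- lab$role == "interaction" & lab$cat == m[1] & lab$cont == m[2]
      if (!any(sel)) next
      expect_lt(abs(sum(pihat[[m[1]]][lab$level[sel]] * fit$theta_hat[sel])),
                1e-10)
    }
  }
})

test_that("estimates are invariant to the null-space basis choice", {
  d <- sim_simple(n = 50, seed = 9)
  des <- constrained_design(simple_spec(), d)
  fit <- fit_ols(des)
  U <- random_orthogonal(ncol(des$Q), seed = 5)
  des_rot <- des
  des_rot$Q <- des$Q %*% U
  des_rot$Z <- des$X %*% des_rot$Q
  fit_rot <- fit_ols(des_rot)
  expect_lt(max(abs(fit$theta_hat - fit_rot$theta_hat)), 1e-8)
  expect_lt(max(abs(fit$vcov - fit_rot$vcov)), 1e-8)
})

test_that("vcov is PSD with rank P - m and se match explicit matrix algebra", {
  d <- sim_simple(n = 40, seed = 2)
  des <- constrained_design(simple_spec(), d)
  fit <- fit_ols(des)
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  expect_equal(sum(ev > 1e-10 * max(ev)), ncol(des$X) - nrow(des$C))
  # oracle: explicit reduced-problem covariance
  V <- fit$sigma2_hat * des$Q %*% solve(crossprod(des$Z)) %*% t(des$Q)
  expect_lt(max(abs(sqrt(diag(V)) - fit$se)), 1e-10)
})

test_that("two equal-sized groups give equal and opposite level effects", {
  set.seed(8)
  n <- 60
  d <- data.frame(y = rnorm(n), x = rnorm(n),
                  g = rep(c("M", "F"), each = n / 2))
  sp <- model_spec("y", "x", list(g = c("M", "F")), modifiers = "none",
                   scheme = "ABC")
  fit <- fit_ols(constrained_design(sp, d))
  b <- fit$theta_hat[fit$labels$role == "level"]
  expect_equal(unname(b[1]), -unname(b[2]), tolerance = 1e-12)
  se <- fit$se[fit$labels$role == "level"]
  expect_equal(unname(se[1]), unname(se[2]), tolerance = 1e-12)
})

test_that("inference table covers every level and uses the t reference", {
  d <- sim_simple(n = 40, seed = 4)
  des <- constrained_design(simple_spec(), d)
  fit <- fit_ols(des)
  inf <- coefficient_inference(fit)
  expect_equal(nrow(inf), 8)                  # no omitted reference row
  expect_equal(inf$p_value,
               2 * pt(abs(inf$t_stat), fit$df, lower.tail = FALSE))
  qt95 <- qt(0.975, fit$df)
  expect_equal(inf$ci_upper - inf$estimate, qt95 * inf$se, tolerance = 1e-12)
  adj <- coefficient_inference(fit, p_adjust = "bonferroni")
  expect_true(all(adj$p_value >= inf$p_value - 1e-15))
})

test_that("group slopes combine main and interaction terms with ABC averaging", {
  d <- sim_simple(n = 60, seed = 6, gamma = c(0.5, -0.5, 0))
  des <- constrained_design(simple_spec(), d)
  fit <- fit_ols(des)
  sl <- group_slopes(fit)
  lab <- fit$labels
  alpha <- unname(fit$theta_hat[lab$role == "main"])
  avg_row <- sl[is.na(sl$level), ]
  expect_equal(avg_row$slope, alpha)
  # per-level slope = alpha + gamma
  for (r in c("A", "B", "C")) {
    gam <- unname(fit$theta_hat[lab$role == "interaction" & lab$level == r])
    expect_equal(sl$slope[!is.na(sl$level) & sl$level == r], alpha + gam)
  }
  # ABC identity: proportion-weighted slopes average to alpha
  pihat <- des$proportions$g
  lvl <- sl[!is.na(sl$level), ]
  expect_lt(abs(sum(pihat[lvl$level] * lvl$slope) - alpha), 1e-10)
  # zero modifiers -> every slope equals alpha
  d0 <- sim_simple(n = 200, seed = 7, gamma = c(0, 0, 0), sd = 0)
  f0 <- fit_ols(constrained_design(simple_spec(), d0))
  s0 <- group_slopes(f0)
  expect_equal(s0$slope, rep(2, 4), tolerance = 1e-8)
})

test_that("published slope identities hold: alpha + gamma gives group slope", {
  expect_equal(-0.032 + -0.038, -0.070)
  sl <- canonical_effects(nc_ri_published()$abc)$slopes$race$RI
  expect_equal(unname(sl["NHB"]), -0.070, tolerance = 1e-12)
})

test_that("variance diagnostic computes scaled within-group variances", {
  d <- data.frame(y = rnorm(6), x = c(1, 2, 3, 5, 5, 5),
                  g = c("A", "A", "A", "B", "B", "B"))
  sp <- model_spec("y", "x", list(g = c("A", "B")), modifiers = "none")
  vd <- variance_diagnostic(d, sp)
  a <- vd[vd$level == "A", ]
  expect_equal(a$sum_sq, 14)
  expect_equal(a$mean_x, 2)
  expect_equal(a$scaled_var, 14 / 3 - 4)
  expect_equal(vd$scaled_var[vd$level == "B"], 0)  # constant group
  # within-group standardization makes all scaled variances exactly 1
  d2 <- sim_simple(n = 90, seed = 10)
  for (gg in unique(d2$g)) {
    i <- d2$g == gg
    m <- mean(d2$x[i]); s <- sqrt(mean((d2$x[i] - m)^2))
    d2$x[i] <- (d2$x[i] - m) / s
  }
  vd2 <- variance_diagnostic(d2, simple_spec())
  expect_equal(vd2$scaled_var, rep(1, 3), tolerance = 1e-12)
})

test_that("exact equal-variance condition gives exact ABC invariance", {
  # skewed proportions: under uniform groups sum-to-zero nearly coincides
  # with the abundance constraint, which would mask the contrast
  d <- sim_simple(n = 120, seed = 12, gamma = c(1.5, -1, -0.5),
                  prob = c(0.6, 0.3, 0.1))
  for (gg in unique(d$g)) {
    i <- d$g == gg
    m <- mean(d$x[i]); s <- sqrt(mean((d$x[i] - m)^2))
    d$x[i] <- (d$x[i] - m) / s
  }
  rep_abc <- invariance_report(simple_spec("ABC"), d)
  expect_lt(rep_abc$comparison$abs_diff, 1e-8)
  # same data under RGE and STZ: invariance fails
  rep_rge <- invariance_report(simple_spec("RGE"), d)
  rep_stz <- invariance_report(simple_spec("STZ"), d)
  expect_gt(rep_rge$comparison$abs_diff, 0.01)
  expect_gt(rep_stz$comparison$abs_diff, 0.01)
})

test_that("OLS estimator is unbiased over Gaussian-noise replicates", {
  set.seed(20)
  n <- 60
  g <- sample(c("A", "B", "C"), n, TRUE); g[1:3] <- c("A", "B", "C")
  x <- rnorm(n)
  sp <- simple_spec()
  d0 <- data.frame(y = 0, x = x, g = g)
  des <- constrained_design(sp, d0)
  pihat <- des$proportions$g
  beta_true <- c(A = 1, B = -1, C = 0)
  beta_true["C"] <- -sum(pihat[c("A", "B")] * beta_true[c("A", "B")]) /
    pihat[["C"]]
  gamma_true <- c(A = 0.5, B = 0, C = 0)
  gamma_true["C"] <- -sum(pihat[c("A", "B")] * gamma_true[c("A", "B")]) /
    pihat[["C"]]
  theta_true <- c(1, 2, beta_true, gamma_true)
  mu <- drop(des$X %*% theta_true)
  R <- 500
  est <- matrix(NA_real_, R, 8)
  for (r in seq_len(R)) {
    fit <- fit_ols(des, y = mu + rnorm(n))
    est[r, ] <- fit$theta_hat
  }
  bias <- colMeans(est) - theta_true
  mc_se <- apply(est, 2, sd) / sqrt(R)
  expect_true(all(abs(bias) <= 3 * mc_se))
})

test_that("degenerate fits are rejected with informative errors", {
  d <- sim_simple(n = 30)
  sp_over <- simple_spec("OVER")
  des <- constrained_design(sp_over, d)
  expect_error(fit_ols(des), "overparametrized")
  # collinear design (duplicated covariate)
  d2 <- d; d2$x2 <- d2$x
  sp2 <- model_spec("y", c("x", "x2"), list(g = c("A", "B", "C")),
                    modifiers = "none", scheme = "ABC")
  expect_error(fit_ols(constrained_design(sp2, d2)), "rank-deficient")
  # too few observations
  expect_error(fit_ols(constrained_design(simple_spec(), d[1:5, ])), "n > P")
})
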