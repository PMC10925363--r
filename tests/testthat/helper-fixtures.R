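# Small synthetic fixtures used across test files.

# One categorical, one continuous, optional modifier effect.
sim_simple <- function(n = 60, levels = c("A", "B", "C"),
                       prob = NULL, beta = NULL, gamma = NULL,
                       alpha0 = 1, alpha1 = 2, sd = 1, seed = 1) {
  set.seed(seed)
  K <- length(levels)
  if (is.null(prob)) prob <- rep(1 / K, K)
  if (is.null(beta)) beta <- seq(-1, 1, length.out = K)
  if (is.null(gamma)) gamma <- rep(0, K)
  g <- sample(levels, n, replace = TRUE, prob = prob)
  # guarantee at least two observations per level (a singleton level makes
  # its indicator and interaction columns collinear)
  g[seq_len(2 * K)] <- rep(levels, 2)
  x <- rnorm(n)
  idx <- match(g, levels)
  y <- alpha0 + alpha1 * x + beta[idx] + gamma[idx] * x + rnorm(n, sd = sd)
  data.frame(y = y, x = x, g = g, stringsAsFactors = FALSE)
}

simple_spec <- function(scheme = "ABC", modifiers = "all",
                        levels = c("A", "B", "C"), reference = levels[1]) {
  model_spec("y", "x", list(g = levels), modifiers = modifiers,
             scheme = scheme,
             reference_levels = if (scheme == "RGE") c(g = reference))
}

# Randomized multi-covariate, multi-categorical spec + matching data.
random_problem <- function(seed, n = 80) {
  set.seed(seed)
  p <- sample(1:3, 1)
  K1 <- sample(2:4, 1)
  two_cats <- runif(1) < 0.4
  conts <- paste0("x", seq_len(p))
  lev1 <- LETTERS[seq_len(K1)]
  cats <- list(g1 = lev1)
  if (two_cats) cats$g2 <- c("u", "v")
  n_mod <- sample(0:p, 1)
  modifiers <- if (n_mod == 0) "none" else
    lapply(sample(conts, n_mod), function(xx) c("g1", xx))
  d <- data.frame(matrix(rnorm(n * p), n, p))
  names(d) <- conts
  d$g1 <- sample(lev1, n, replace = TRUE)
  d$g1[seq_along(lev1)] <- lev1
  if (two_cats) {
    d$g2 <- sample(c("u", "v"), n, replace = TRUE)
    d$g2[1:2] <- c("u", "v")
  }
  d$y <- rnorm(n) + rowSums(d[conts])
  spec <- model_spec("y", conts, cats, modifiers = modifiers, scheme = "ABC")
  list(spec = spec, data = d)
}

# Random orthogonal matrix (for basis-rotation invariance checks).
random_orthogonal <- function(k, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(k * k), k, k)))
}
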