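# Independent oracles: each solves the estimation problem by a route that
# never touches the package's QR-null-space path.

# Equality-constrained least squares via the KKT linear system
#   [2 X'X  C'] [theta]   [2 X'y]
#   [  C    0 ] [ nu  ] = [  0  ]
kkt_ols_oracle <- function(X, y, C) {
  P <- ncol(X); m <- nrow(C)
  K <- rbind(cbind(2 * crossprod(X), t(C)),
             cbind(C, matrix(0, m, m)))
  rhs <- c(2 * crossprod(X, y), rep(0, m))
  drop(solve(K, rhs))[seq_len(P)]
}

# Equality-constrained weighted ridge via its KKT system:
# min ||y - X theta||^2 + lambda sum omega theta^2  s.t.  C theta = 0
kkt_ridge_oracle <- function(X, y, C, lambda, omega) {
  P <- ncol(X); m <- nrow(C)
  K <- rbind(cbind(2 * crossprod(X) + 2 * lambda * diag(omega), t(C)),
             cbind(C, matrix(0, m, m)))
  rhs <- c(2 * crossprod(X, y), rep(0, m))
  drop(solve(K, rhs))[seq_len(P)]
}

# Null-space projector from an independent SVD route.
svd_null_projector <- function(C) {
  s <- svd(C, nu = 0, nv = ncol(C))
  r <- sum(s$d > max(dim(C)) * max(s$d) * .Machine$double.eps)
  V1 <- s$v[, seq_len(r), drop = FALSE]
  diag(ncol(C)) - V1 %*% t(V1)
}

# Projection of y onto the column space of X (fitted values of an
# unconstrained least-squares fit), via SVD.
colspace_projection <- function(X, y) {
  s <- svd(X)
  keep <- s$d > max(dim(X)) * max(s$d) * .Machine$double.eps
  U <- s$u[, keep, drop = FALSE]
  drop(U %*% crossprod(U, y))
}

# Constrained weighted lasso objective.
lasso_objective <- function(theta, X, y, lambda, omega) {
  sum((y - drop(X %*% theta))^2) + lambda * sum(omega * abs(theta))
}

# Subgradient optimality certificate for the constrained weighted lasso at
# theta (in reduced coordinates the condition is
#   Q' (2 X'(X theta - y) + lambda omega s) = 0,  s in the subdifferential).
# Signs are fixed on coordinates with |theta| > act_tol; the free s values
# are found by least squares and must land in [-1, 1] with a small residual.
lasso_subgradient_check <- function(theta, X, y, lambda, omega, Q,
                                    act_tol = 1e-6, tol = 1e-4) {
  g <- 2 * crossprod(X, drop(X %*% theta) - y)     # loss gradient wrt theta
  active <- abs(theta) > act_tol
  s <- sign(theta)
  target <- -crossprod(Q, g + lambda * omega * s * active)
  Afree <- crossprod(Q, diag(lambda * omega))[, !active, drop = FALSE]
  if (any(!active)) {
    # minimum-norm solve (the system may be under-determined)
    sv <- svd(Afree)
    keep <- sv$d > max(dim(Afree)) * max(sv$d) * .Machine$double.eps
    s_free <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], target)) / sv$d[keep])
    resid <- max(abs(Afree %*% s_free - target))
    list(ok = resid < tol * max(1, lambda) && all(abs(s_free) <= 1 + tol),
         resid = resid, max_s = if (length(s_free)) max(abs(s_free)) else 0)
  } else {
    resid <- max(abs(target))
    list(ok = resid < tol * max(1, lambda), resid = resid, max_s = 0)
  }
}

# Independent convex solve of the constrained weighted lasso through the
# positive/negative split QP, using scipy's SLSQP via the python CLI.
scipy_lasso_oracle <- function(X, y, C, lambda, omega, theta_init = NULL) {
  dir <- tempfile("lassoqp"); dir.create(dir)
  utils::write.table(X, file.path(dir, "X.txt"), row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(C, file.path(dir, "C.txt"), row.names = FALSE,
                     col.names = FALSE)
  writeLines(format(c(length(y), lambda), digits = 17),
             file.path(dir, "meta.txt"))
  writeLines(format(y, digits = 17), file.path(dir, "y.txt"))
  writeLines(format(omega, digits = 17), file.path(dir, "w.txt"))
  script <- file.path(dir, "solve.py")
  writeLines(c(
    "import numpy as np",
    "from scipy.optimize import minimize",
    "import sys, os",
    "d = sys.argv[1]",
    "X = np.loadtxt(os.path.join(d, 'X.txt'), ndmin=2)",
    "C = np.loadtxt(os.path.join(d, 'C.txt'), ndmin=2)",
    "y = np.loadtxt(os.path.join(d, 'y.txt'))",
    "w = np.loadtxt(os.path.join(d, 'w.txt'))",
    "lam = float(open(os.path.join(d, 'meta.txt')).read().split()[1])",
    "P = X.shape[1]",
    "def f(z):",
    "    th = z[:P] - z[P:]",
    "    r = y - X @ th",
    "    return r @ r + lam * (w @ (z[:P] + z[P:]))",
    "def grad(z):",
    "    th = z[:P] - z[P:]",
    "    g = -2 * X.T @ (y - X @ th)",
    "    return np.concatenate([g + lam * w, -g + lam * w])",
    "cons = [{'type': 'eq',",
    "         'fun': lambda z: C @ (z[:P] - z[P:]),",
    "         'jac': lambda z: np.hstack([C, -C])}] if C.size else []",
    "z0 = np.zeros(2 * P)",
    "res = minimize(f, z0, jac=grad, method='SLSQP', bounds=[(0, None)] * (2 * P),",
    "               constraints=cons, options={'maxiter': 2000, 'ftol': 1e-14})",
    "th = res.x[:P] - res.x[P:]",
    "np.savetxt(os.path.join(d, 'theta.txt'), th)"
  ), script)
  status <- system2("python", c(script, dir), stdout = TRUE, stderr = TRUE)
  out <- file.path(dir, "theta.txt")
  if (!file.exists(out))
    stop("scipy oracle failed: ", paste(status, collapse = "\n"))
  theta <- scan(out, quiet = TRUE)
  unlink(dir, recursive = TRUE)
  theta
}
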