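#' Build the labeled design matrix for a modifier model
#'
#' Expands an observation table into the full (unconstrained) design matrix
#' with one column for the intercept, one per continuous covariate, one
#' indicator column per level of every categorical, and one
#' indicator-times-covariate column per level of every modifier pair.  All
#' declared levels get a column; identifiability comes from the constraint
#' matrix, not from dropping a reference column.
#'
#' Rows with missing values in the outcome or any used covariate are
#' dropped (with a message reporting the count).  When
#' `spec$center_scale` is set, continuous columns are centered and divided
#' by their population-style standard deviation (divisor `n`) before
#' indicators and interactions are formed.
#'
#' @param spec An `abc_model_spec`.
#' @param data Observation table containing all referenced columns.
#' @return A list of class `"abc_design"` with elements `X` (n x P matrix,
#'   labeled columns), `labels` (data.frame with columns `role`
#'   (`intercept`/`main`/`level`/`interaction`), `cat`, `level`, `cont`),
#'   `y` (outcome vector), `spec` (with levels resolved), and `n_dropped`.
#' @export
build_design <- function(spec, data) {
  stopifnot(inherits(spec, "abc_model_spec"), is.data.frame(data))
  spec <- resolve_levels(spec, data)
  used <- c(spec$outcome, spec$continuous, names(spec$categoricals))
  miss <- setdiff(used, names(data))
  if (length(miss)) stop("data is missing column(s): ", paste(miss, collapse = ", "))
  for (xx in spec$continuous)
    if (!is.numeric(data[[xx]]))
      stop("continuous column '", xx, "' is not numeric")
  if (!is.numeric(data[[spec$outcome]]))
    stop("outcome column '", spec$outcome, "' is not numeric")

  keep <- stats::complete.cases(data[used])
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message("build_design: dropped ", n_dropped, " row(s) with missing values")
    data <- data[keep, , drop = FALSE]
  }
  n <- nrow(data)
  if (n == 0L) stop("no complete observations")

  xmat <- as.matrix(data[spec$continuous])
  if (spec$center_scale && length(spec$continuous)) {
    ctr <- colMeans(xmat)
    scl <- sqrt(colMeans(sweep(xmat, 2, ctr)^2))
    if (any(scl == 0)) stop("cannot scale a constant continuous column")
    xmat <- sweep(sweep(xmat, 2, ctr), 2, scl, "/")
  }

  p <- length(spec$continuous)
  cols <- list(`(Intercept)` = rep(1, n))
  lab <- data.frame(role = "intercept", cat = NA_character_,
                    level = NA_character_, cont = NA_character_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    cols[[spec$continuous[j]]] <- xmat[, j]
    lab <- rbind(lab, data.frame(role = "main", cat = NA, level = NA,
                                 cont = spec$continuous[j]))
  }
  for (cc in names(spec$categoricals)) {
    lv <- spec$categoricals[[cc]]
    obs <- as.character(data[[cc]])
    for (r in lv) {
      cols[[paste0(cc, "=", r)]] <- as.numeric(obs == r)
      lab <- rbind(lab, data.frame(role = "level", cat = cc, level = r,
                                   cont = NA))
    }
  }
  for (m in spec$modifiers) {
    cc <- m[1]; xx <- m[2]
    lv <- spec$categoricals[[cc]]
    xv <- xmat[, match(xx, spec$continuous)]
    obs <- as.character(data[[cc]])
    for (r in lv) {
      cols[[paste0(xx, ":", cc, "=", r)]] <- xv * (obs == r)
      lab <- rbind(lab, data.frame(role = "interaction", cat = cc, level = r,
                                   cont = xx))
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  rownames(lab) <- NULL
  structure(list(X = X, labels = lab, y = data[[spec$outcome]],
                 spec = spec, n_dropped = n_dropped),
            class = "abc_design")
}

#' Constraint matrix for an identification scheme
#'
#' One constraint row per categorical variable (over its level-indicator
#' coefficient block) and one per modifier pair (over its interaction
#' block).  Under ABCs the row carries the group proportions; under
#' sum-to-zero, ones; under reference-group encoding, a single one at the
#' reference level's column.  The overparametrized scheme has no
#' constraints (a 0 x P matrix).
#'
#' @param spec An `abc_model_spec` with levels resolved (as returned inside
#'   [build_design()]).
#' @param proportions An `abc_proportions` object (needed for ABC).
#' @param labels Column metadata from [build_design()].
#' @return An m x P numeric matrix with full row rank.
#' @export
build_constraints <- function(spec, proportions, labels) {
  P <- nrow(labels)
  blocks <- list()
  for (cc in names(spec$categoricals))
    blocks[[length(blocks) + 1L]] <- list(cat = cc, cont = NA_character_,
                                          role = "level")
  for (m in spec$modifiers)
    blocks[[length(blocks) + 1L]] <- list(cat = m[1], cont = m[2],
                                          role = "interaction")
  if (identical(spec$scheme, "OVER"))
    return(matrix(0, nrow = 0, ncol = P))
  if (identical(spec$scheme, "RGE") && is.null(spec$reference_levels))
    stop("RGE constraints require reference levels")
  C <- matrix(0, nrow = length(blocks), ncol = P)
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    sel <- labels$role == bl$role & labels$cat == bl$cat &
      (if (is.na(bl$cont)) TRUE else labels$cont == bl$cont)
    sel[is.na(sel)] <- FALSE
    lv <- labels$level[sel]
    C[b, sel] <- switch(spec$scheme,
      ABC = {
        if (is.null(proportions[[bl$cat]]))
          stop("proportions missing for categorical '", bl$cat, "'")
        unname(proportions[[bl$cat]][lv])
      },
      STZ = 1,
      RGE = as.numeric(lv == spec$reference_levels[[bl$cat]])
    )
  }
  C
}

#' Null-space reparametrization of a constrained design
#'
#' Computes an orthonormal basis `Q` of the null space of the constraint
#' matrix via the QR decomposition of its transpose, and the reduced design
#' `Z = X Q`.  Every coefficient vector of the form `theta = Q zeta`
#' satisfies the constraints exactly, so constrained least squares reduces
#' to ordinary least squares on `Z`.
#'
#' @param C m x P constraint matrix with full row rank (m may be 0).
#' @param X n x P design matrix.
#' @return List with `Q` (P x (P-m), orthonormal columns) and `Z`
#'   (n x (P-m)).
#' @export
reparametrize <- function(C, X) {
  P <- ncol(X)
  m <- nrow(C)
  if (m == 0L) {
    Q <- diag(P)
    return(list(Q = Q, Z = X))
  }
  if (ncol(C) != P) stop("constraint matrix width does not match design")
  dec <- qr(t(C))
  if (dec$rank < m)
    stop("constraint matrix is rank-deficient (rank ", dec$rank, " < ", m,
         "): redundant constraints")
  Qfull <- qr.Q(dec, complete = TRUE)
  Q <- Qfull[, (m + 1L):P, drop = FALSE]
  list(Q = Q, Z = X %*% Q)
}

#' Build design, constraints, and reparametrization in one call
#'
#' Convenience constructor producing the complete constrained design:
#' the labeled design matrix, the scheme's constraint matrix, the null-space
#' basis, and the reduced design.
#'
#' @inheritParams build_design
#' @param proportions Optional `abc_proportions`; estimated from the data
#'   when omitted (sample proportions).
#' @return An object of class `"abc_design"` with elements `X`, `labels`,
#'   `y`, `spec`, `proportions`, `C`, `Q`, `Z`.
#' @examples
#' d <- data.frame(y = rnorm(20), x = rnorm(20),
#'                 g = rep(c("A", "B"), 10))
#' sp <- model_spec("y", "x", list(g = NULL), modifiers = "all")
#' des <- constrained_design(sp, d)
#' dim(des$Z)
#' @export
constrained_design <- function(spec, data, proportions = NULL) {
  des <- build_design(spec, data)
  if (is.null(proportions) && identical(spec$scheme, "ABC"))
    proportions <- estimate_proportions(data, des$spec)
  des$proportions <- proportions
  des$C <- build_constraints(des$spec, proportions, des$labels)
  rep <- reparametrize(des$C, des$X)
  des$Q <- rep$Q
  des$Z <- rep$Z
  des
}

#' @export
print.abc_design <- function(x, ...) {
  cat("Constrained design: n =", nrow(x$X), ", P =", ncol(x$X),
      if (!is.null(x$C)) paste0(", m = ", nrow(x$C),
                                " (", x$spec$scheme, ")"), "\n")
  invisible(x)
}
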