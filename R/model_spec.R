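#' Declare a race-modified (or general categorical-modifier) linear model
#'
#' A model specification names the outcome, the continuous covariates, the
#' categorical covariates with their level sets, the modifier pairs
#' (categorical-by-continuous interactions to include), and the
#' identification scheme used to make the categorical blocks estimable.
#'
#' Four identification schemes are supported:
#' \describe{
#'   \item{`"ABC"`}{abundance-based constraints: each categorical block of
#'     coefficients (and each interaction block) averages to zero under the
#'     group proportions, so main effects are proportion-weighted averages
#'     of group-specific effects.}
#'   \item{`"RGE"`}{reference-group encoding: one level's coefficients are
#'     pinned to zero; "main effects" are then reference-group-specific.}
#'   \item{`"STZ"`}{sum-to-zero: unweighted block sums are zero.}
#'   \item{`"OVER"`}{overparametrized: no constraints; only valid for
#'     penalized estimation.}
#' }
#'
#' @param outcome Name of the outcome column.
#' @param continuous Character vector of continuous covariate columns (order
#'   fixes the column layout of the design matrix).
#' @param categoricals Named list: one entry per categorical covariate,
#'   either `NULL`/`NA` (levels taken in order of first appearance in the
#'   data) or a character vector of declared levels (at least two).
#' @param modifiers List of `c(categorical, continuous)` pairs naming the
#'   interactions to include, or the string `"all"` for every pair.
#' @param scheme One of `"ABC"`, `"RGE"`, `"STZ"`, `"OVER"`.
#' @param reference_levels Named character vector mapping each categorical
#'   to its reference level; required for `"RGE"`, ignored otherwise.
#' @param center_scale Logical; standardize the continuous covariates
#'   (center, divide by the population-style standard deviation) before the
#'   design matrix is built.
#'
#' @return An object of class `"abc_model_spec"`.
#' @examples
#' spec <- model_spec(
#'   outcome = "score", continuous = "RI",
#'   categoricals = list(race = c("NHW", "NHB", "Hisp")),
#'   modifiers = "all", scheme = "ABC"
#' )
#' @export
model_spec <- function(outcome, continuous, categoricals,
                       modifiers = "all",
                       scheme = c("ABC", "RGE", "STZ", "OVER"),
                       reference_levels = NULL,
                       center_scale = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(is.character(outcome), length(outcome) == 1L)
  continuous <- as.character(continuous)
  if (anyDuplicated(c(outcome, continuous, names(categoricals))))
    stop("duplicate column labels in model specification")
  if (!is.list(categoricals) || is.null(names(categoricals)) ||
      any(!nzchar(names(categoricals))))
    stop("'categoricals' must be a named list (name = column label)")
  categoricals <- lapply(categoricals, function(lv) {
    if (is.null(lv) || (length(lv) == 1L && is.na(lv))) return(NULL)
    lv <- as.character(lv)
    if (length(lv) < 2L) stop("every categorical needs at least 2 declared levels")
    if (anyDuplicated(lv)) stop("duplicate levels declared for a categorical")
    lv
  })
  if (identical(modifiers, "all")) {
    modifiers <- unlist(lapply(names(categoricals), function(cc)
      lapply(continuous, function(xx) c(cc, xx))), recursive = FALSE)
  } else if (identical(modifiers, "none") || length(modifiers) == 0L) {
    modifiers <- list()
  }
  modifiers <- lapply(modifiers, function(m) {
    m <- as.character(m)
    if (length(m) != 2L) stop("each modifier must be a (categorical, continuous) pair")
    if (!m[1] %in% names(categoricals))
      stop("modifier references undeclared categorical: ", m[1])
    if (!m[2] %in% continuous)
      stop("modifier references undeclared continuous covariate: ", m[2])
    m
  })
  if (scheme == "RGE") {
    if (is.null(reference_levels) || is.null(names(reference_levels)) ||
        !all(names(categoricals) %in% names(reference_levels)))
      stop("RGE requires a reference level for every categorical")
    reference_levels <- reference_levels[names(categoricals)]
    for (cc in names(categoricals)) {
      lv <- categoricals[[cc]]
      if (!is.null(lv) && !reference_levels[[cc]] %in% lv)
        stop("reference level '", reference_levels[[cc]],
             "' is not a declared level of '", cc, "'")
    }
  }
  structure(
    list(outcome = outcome, continuous = continuous,
         categoricals = categoricals, modifiers = modifiers,
         scheme = scheme, reference_levels = reference_levels,
         center_scale = isTRUE(center_scale)),
    class = "abc_model_spec"
  )
}

#' @export
print.abc_model_spec <- function(x, ...) {
  cat("Model specification (", x$scheme, ")\n", sep = "")
  cat("  outcome:    ", x$outcome, "\n")
  cat("  continuous: ", paste(x$continuous, collapse = ", "), "\n")
  for (cc in names(x$categoricals)) {
    lv <- x$categoricals[[cc]]
    cat("  categorical:", cc,
        if (is.null(lv)) "(levels from data)" else paste(lv, collapse = "/"), "\n")
  }
  if (length(x$modifiers))
    cat("  modifiers:  ",
        paste(vapply(x$modifiers, function(m) paste(m[2], m[1], sep = ":"),
                     character(1)), collapse = ", "), "\n")
  invisible(x)
}

#' Drop the modifier terms from a model specification
#'
#' Returns the main-only counterpart of a modified model: same outcome,
#' covariates, categoricals and scheme, with no interaction terms.
#'
#' @param spec An `abc_model_spec`.
#' @return An `abc_model_spec` without modifiers.
#' @export
drop_modifiers <- function(spec) {
  stopifnot(inherits(spec, "abc_model_spec"))
  spec$modifiers <- list()
  spec
}

# Resolve data-driven level sets against an observation table; returns the
# spec with every categorical's levels filled in (order of first appearance).
resolve_levels <- function(spec, data) {
  for (cc in names(spec$categoricals)) {
    if (!cc %in% names(data)) stop("categorical column not in data: ", cc)
    obs <- as.character(data[[cc]])
    if (is.null(spec$categoricals[[cc]])) {
      spec$categoricals[[cc]] <- unique(obs)
      if (length(spec$categoricals[[cc]]) < 2L)
        stop("categorical '", cc, "' has fewer than 2 observed levels")
    } else {
      extra <- setdiff(obs, spec$categoricals[[cc]])
      if (length(extra))
        stop("undeclared level(s) in '", cc, "': ",
             paste(extra, collapse = ", "))
    }
  }
  if (identical(spec$scheme, "RGE")) {
    for (cc in names(spec$categoricals)) {
      if (!spec$reference_levels[[cc]] %in% spec$categoricals[[cc]])
        stop("reference level '", spec$reference_levels[[cc]],
             "' not among levels of '", cc, "'")
    }
  }
  spec
}
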