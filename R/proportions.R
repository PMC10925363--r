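#' Group proportions for abundance-based constraints
#'
#' ABCs weight each categorical coefficient block by the abundance of its
#' groups.  Proportions may be estimated from the sample (the default) or
#' supplied externally, e.g. census population shares.  With multiple
#' categorical covariates the constraints use the per-variable marginal
#' proportions; a supplied joint table is marginalized.
#'
#' @param data Observation table (data.frame) containing the categorical
#'   columns, or `NULL` when `supplied` covers every categorical.
#' @param spec An `abc_model_spec`.
#' @param supplied Optional proportions: a named list with one entry per
#'   categorical variable, each a named numeric vector over that variable's
#'   levels summing to 1.
#'
#' @return An object of class `"abc_proportions"`: a named list of per-level
#'   weight vectors with attribute `source` (`"sample"` or `"supplied"`).
#' @examples
#' d <- data.frame(race = c("A", "A", "B", "C"))
#' sp <- model_spec("y", character(0), list(race = NULL), modifiers = "none")
#' estimate_proportions(d, sp)
#' @export
estimate_proportions <- function(data, spec, supplied = NULL) {
  stopifnot(inherits(spec, "abc_model_spec"))
  if (!is.null(supplied)) {
    if (!is.list(supplied) || is.null(names(supplied)))
      stop("'supplied' must be a named list of per-variable proportion vectors")
    out <- list()
    for (cc in names(spec$categoricals)) {
      if (!cc %in% names(supplied))
        stop("supplied proportions missing categorical '", cc, "'")
      p <- supplied[[cc]]
      lv <- spec$categoricals[[cc]]
      if (is.null(lv)) lv <- names(p)
      if (is.null(names(p)) || !setequal(names(p), lv))
        stop("supplied proportions for '", cc,
             "' must cover exactly the declared levels")
      p <- p[lv]
      if (any(p <= 0)) stop("supplied proportions must be strictly positive")
      if (abs(sum(p) - 1) > 1e-8)
        stop("supplied proportions for '", cc, "' sum to ", format(sum(p)),
             ", not 1")
      out[[cc]] <- p
    }
    return(structure(out, source = "supplied", class = "abc_proportions"))
  }
  if (is.null(data)) stop("either data or supplied proportions are required")
  spec <- resolve_levels(spec, data)
  out <- list()
  for (cc in names(spec$categoricals)) {
    lv <- spec$categoricals[[cc]]
    cnt <- table(factor(as.character(data[[cc]]), levels = lv))
    if (any(cnt == 0L))
      stop("declared level '", lv[which(cnt == 0L)[1]],
           "' of '", cc, "' is absent from the data; ",
           "supply proportions explicitly")
    p <- as.numeric(cnt) / sum(cnt)
    names(p) <- lv
    out[[cc]] <- p
  }
  structure(out, source = "sample", class = "abc_proportions")
}

#' @export
print.abc_proportions <- function(x, ...) {
  cat("Group proportions (source: ", attr(x, "source"), ")\n", sep = "")
  for (cc in names(x)) {
    cat("  ", cc, ": ",
        paste(sprintf("%s=%.4g", names(x[[cc]]), x[[cc]]), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
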