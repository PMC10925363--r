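#' Published NC racial-isolation regression coefficients
#'
#' The published race-modified regression of 4th-grade end-of-grade reading
#' scores on racial isolation (RI) for North Carolina students
#' (`y ~ 1 + RI + race + RI:race`, race groups NH White / NH Black /
#' Hispanic) was reported twice: once under default reference-group
#' encoding (reference NH White) and once under abundance-based
#' constraints with the cohort's race proportions 58% / 36% / 6%.  This
#' helper loads both printed coefficient columns (3-decimal precision) as
#' coefficient sets, for use in scheme-conversion worked examples and
#' checks.  The underlying microdata are privacy-restricted and are not
#' part of this package.
#'
#' @return A list with elements `rge` and `abc` (both
#'   `"abc_coefficients"`) and `proportions`.
#' @examples
#' pub <- nc_ri_published()
#' convert_scheme(pub$rge, "ABC")
#' @export
nc_ri_published <- function() {
  path <- system.file("extdata", "nc_ri_published_coefficients.tsv",
                      package = "abcreg", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA")
  proportions <- list(race = c(NHW = 0.58, NHB = 0.36, Hisp = 0.06))
  build <- function(scheme) {
    t0 <- tab[tab$scheme == scheme, ]
    beta <- t0$estimate[t0$role == "level"]
    names(beta) <- t0$level[t0$role == "level"]
    gam <- t0$estimate[t0$role == "interaction"]
    names(gam) <- t0$level[t0$role == "interaction"]
    coefficient_set(
      scheme = scheme,
      alpha0 = t0$estimate[t0$role == "intercept"],
      alpha = c(RI = t0$estimate[t0$role == "main"]),
      beta = list(race = beta),
      gamma = list(race = list(RI = gam)),
      proportions = proportions,
      reference_levels = if (scheme == "RGE") c(race = "NHW"),
      check = FALSE)   # printed values are rounded to 3 decimals
  }
  list(rge = build("RGE"), abc = build("ABC"), proportions = proportions)
}
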