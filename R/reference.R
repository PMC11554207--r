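#' Published locality-average contamination indices
#'
#' Loads the packaged reference table of locality-average contamination
#' indices (mean and standard deviation of `CIe`, `CIb`, `CIa`, `CIsq`,
#' `CIr` per locality and gear) reported for fish assemblages of the upper
#' Parana River floodplain monitored from 2000 to 2017.  Values are printed
#' to two decimals.  The table serves as an internal-consistency surface:
#' the additive index is linear in its components, so
#' `ci_additive(CIb, CIr)` must reproduce the printed `CIa` at two
#' decimals, and the geometric form `ci_multiplicative(CIb, CIr)` the
#' printed `CIsq`.
#'
#' @return A tibble with 15 rows and columns `locality`, `method`, and
#'   mean/sd pairs for the five indices.
#' @examples
#' ref <- reference_locality_ci()
#' with(ref[ref$locality == "lgua" & ref$method == "gillnet", ],
#'      ci_additive(CIb, CIr))
#' @export
reference_locality_ci <- function() {
  path <- system.file("extdata", "parana_locality_ci.csv",
                      package = "floodcontam", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
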