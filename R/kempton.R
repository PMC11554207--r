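#' Kempton's Q interquartile biomass diversity
#'
#' Kempton's Q for one locality's assemblage, computed from the per-species
#' biomass distribution: `Q = (R / 2) / ln(B4 / B2)`, where `R` is the
#' species richness and `B4`, `B2` are the 75th and 25th percentiles of the
#' per-species biomass vector under linear interpolation between order
#' statistics (quantile type 7).  Q grows with richness and with evenness
#' (a narrow interquartile biomass ratio), and is invariant to rescaling all
#' biomasses by a positive constant.
#'
#' Q is undefined (returned as `NA`) when the upper and lower quartiles
#' coincide, e.g. when all species have equal biomass.  Non-positive
#' biomasses are an error: a species with no biomass is not part of an
#' assemblage.
#'
#' @param biomass Vector of per-species biomass values (> 0) for one
#'   locality and origin class.
#' @return Q (dimensionless), or `NA` when undefined.
#' @examples
#' kempton_q(c(rep(1, 5), rep(exp(1), 5)))  # 10/2 / ln(e) = 5
#' @export
kempton_q <- function(biomass) {
  if (length(biomass) == 0) return(NA_real_)
  if (any(!is.finite(biomass) | biomass <= 0)) {
    stop("all biomass values must be finite and > 0", call. = FALSE)
  }
  r <- length(biomass)
  b2 <- quantile(biomass, 0.25, type = 7, names = FALSE)
  b4 <- quantile(biomass, 0.75, type = 7, names = FALSE)
  if (b4 <= b2) return(NA_real_)
  (r / 2) / log(b4 / b2)
}

#' Campaign-level Kempton's Q across localities
#'
#' Averages per-locality Q values for one campaign and origin class.
#' Localities with undefined Q (degenerate biomass distributions) are
#' skipped and counted, not coerced to zero.
#'
#' @param biomass_by_locality A list of per-species biomass vectors, one
#'   element per locality (names are locality codes), or a numeric vector of
#'   already-computed per-locality Q values.
#' @return A list of class `kempton_result`: `Q` (mean over defined
#'   localities, `NA` when none is defined), `k` (number contributing), and
#'   `n_skipped`.
#' @examples
#' kempton_q_campaign(c(4, 6))  # Q = 5, k = 2
#' @export
kempton_q_campaign <- function(biomass_by_locality) {
  q <- if (is.list(biomass_by_locality)) {
    vapply(biomass_by_locality, kempton_q, numeric(1))
  } else {
    as.numeric(biomass_by_locality)
  }
  defined <- !is.na(q)
  structure(
    list(Q = if (any(defined)) mean(q[defined]) else NA_real_,
         k = sum(defined), n_skipped = sum(!defined)),
    class = "kempton_result"
  )
}

#' @export
print.kempton_result <- function(x, ...) {
  cat(sprintf("Kempton's Q = %s (k = %d localities, %d skipped)\n",
              ifelse(is.na(x$Q), "undefined", sprintf("%.4f", x$Q)),
              x$k, x$n_skipped))
  invisible(x)
}
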