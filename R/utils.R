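#' Round half away from zero
#'
#' Rounds to a fixed number of decimal places with ties going away from
#' zero, the convention used for printed report tables (base [round()]
#' rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_away(0.585, 2)  # 0.59, where round() gives 0.58
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Meteorological quarter of a date, as integer 1..4.
quarter_of <- function(dates) {
  (as.integer(format(as.Date(dates), "%m")) - 1L) %/% 3L + 1L
}

# Campaign label "YYYY-Qq" for a vector of dates.
campaign_of <- function(dates) {
  sprintf("%s-Q%d", format(as.Date(dates), "%Y"), quarter_of(dates))
}

# Fractional years since the earliest date in `origin` (default: min of x).
years_since <- function(dates, origin = NULL) {
  dates <- as.Date(dates)
  origin <- as.Date(origin %||% min(dates))
  as.numeric(dates - origin) / 365.25
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
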