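#' Parameter-recovery report for a simulated survey
#'
#' Compares the contamination trajectory estimated from the emitted survey
#' against the simulator's realized true state: per-unit richness
#' contamination `CI_r` against the true resident non-native fraction of
#' the same locality and campaign.  Reports the mean signed bias, the RMSE,
#' and whether the estimated and true per-campaign trend slopes agree in
#' sign.
#'
#' @param sim A `sim_survey` from [simulate_survey()], or a truth tibble
#'   (then `survey` must be given).
#' @param survey Optional `survey_table` when `sim` is a truth tibble.
#' @return A list of class `recovery_report`: `n` (matched units), `bias`,
#'   `rmse`, `est_slope`, `true_slope`, `sign_agreement`.
#' @export
recovery_report <- function(sim, survey = NULL) {
  if (inherits(sim, "sim_survey")) {
    truth <- sim$truth
    survey <- sim$survey
  } else {
    truth <- sim
    if (is.null(survey)) stop("survey required when sim is a truth table",
                              call. = FALSE)
  }
  us <- contamination_indices(summarize_units(survey))
  matched <- us %>%
    inner_join(truth[c("locality", "campaign", "frac_nonnative")],
               by = c("locality", "campaign"))
  if (nrow(matched) < nrow(us)) {
    stop("mismatched keys: ", nrow(us) - nrow(matched),
         " sampling unit(s) have no matching (locality, campaign) in the",
         " true state", call. = FALSE)
  }
  ok <- !is.na(matched$CI_r)
  dev <- matched$CI_r[ok] - matched$frac_nonnative[ok]

  slope_of <- function(d, col) {
    s <- d %>%
      group_by(.data$campaign) %>%
      summarise(y = mean(.data[[col]], na.rm = TRUE),
                t = mean(.data$time), .groups = "drop")
    unname(coef(lm(y ~ t, data = s))[["t"]])
  }
  est_slope <- slope_of(matched[ok, ], "CI_r")
  true_slope <- slope_of(truth, "frac_nonnative")
  near0 <- function(x) abs(x) < 1e-6

  structure(
    list(n = sum(ok), bias = mean(dev), rmse = sqrt(mean(dev^2)),
         est_slope = est_slope, true_slope = true_slope,
         sign_agreement = (near0(est_slope) && near0(true_slope)) ||
           sign(est_slope) == sign(true_slope)),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  cat(sprintf("  n = %d units; bias = %.4f; rmse = %.4f\n", x$n, x$bias,
              x$rmse))
  cat(sprintf("  slopes: estimated %.4g vs true %.4g (sign agreement: %s)\n",
              x$est_slope, x$true_slope, x$sign_agreement))
  invisible(x)
}
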