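#' Plot a fitted temporal trend
#'
#' Observed values (points) with the fitted population-level smooth (line)
#' from a [fit_smooth_trend()] object.
#'
#' @param fit A `trend_fit`.
#' @return A ggplot object.
#' @export
plot_trend <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  d <- tibble(time = fit$time, response = fit$response,
              fitted = fit$fitted)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$response),
                        alpha = 0.4, size = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linewidth = 0.9,
                       colour = "#b2182b") +
    ggplot2::labs(x = "Time (years)",
                  y = if (fit$transform == "log10p1")
                    "log10(response + 1)" else "Response",
                  title = fit$label %||% "Temporal trend",
                  subtitle = sprintf(
                    "edf = %.2f, p = %.3g, beta = %.3g/yr, phi = %.2f",
                    fit$edf, fit$p, fit$beta, fit$phi)) +
    ggplot2::theme_minimal()
}

#' Plot locality-average contamination indices
#'
#' Dot-and-whisker panel of the five mean contamination indices per
#' locality and gear, from the output of
#' `aggregate_series(survey, by = "locality")`.
#'
#' @param series A locality-level metric series (one row per locality,
#'   gear and origin; index columns `CIe`, `CIb`, `CIa`, `CIsq`, `CIr`).
#' @return A ggplot object.
#' @export
plot_contamination <- function(series) {
  d <- series %>%
    filter(.data$origin == "native") %>%  # CI columns repeat across origins
    tidyr::pivot_longer(cols = c("CIe", "CIb", "CIa", "CIsq", "CIr"),
                        names_to = "index", values_to = "value") %>%
    filter(is.finite(.data$value))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$locality, y = .data$value,
                                  colour = .data$index)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~gear) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Mean contamination index",
                  colour = "Index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
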