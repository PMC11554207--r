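#' Area-standardised biomass
#'
#' Biomass density of a catch: total weight of all individuals divided by the
#' sampled area, in g m^-2.
#'
#' @param total_weight_g Total weight in grams (>= 0), possibly a vector.
#' @param area_m2 Sampled area in m^2 (> 0), recycled against the weights.
#' @return Biomass density in g m^-2.
#' @examples
#' biomass_density(368, 368)          # one gram per square metre
#' biomass_density(100 + 50 + 25, 250)
#' @export
biomass_density <- function(total_weight_g, area_m2) {
  if (any(!is.finite(area_m2) | area_m2 <= 0)) {
    stop("area_m2 must be > 0", call. = FALSE)
  }
  if (any(is.finite(total_weight_g) & total_weight_g < 0)) {
    stop("total_weight_g must be >= 0", call. = FALSE)
  }
  total_weight_g / area_m2
}

#' Per-unit assemblage summaries
#'
#' Summarises every sampling unit of a survey into the quantities all
#' contamination indices are built from: native and non-native species
#' richness (`R_n`, `R_nn`; distinct species with at least one individual)
#' and native and non-native biomass density (`B_n`, `B_nn`; sum of
#' per-species densities, g m^-2).  Unclassified species are excluded from
#' both origin classes.  Units with no catches yield all-zero summaries.
#'
#' @param survey A validated `survey_table`.
#' @param check Run [validate_survey()] first and refuse a survey with
#'   errors (default `TRUE`).
#' @return A tibble with one row per sampling unit: unit keys (`unit_id`,
#'   `locality`, `habitat`, `gear`, `campaign_date`, `campaign`, `season`,
#'   `time`, `area_m2`) plus `R_n`, `R_nn`, `B_n`, `B_nn`, and totals `R_s`,
#'   `B_s` over the two classified origin classes.
#' @export
summarize_units <- function(survey, check = TRUE) {
  stopifnot(inherits(survey, "survey_table"))
  if (check) assert_valid(survey)
  keys <- survey$units %>%
    select("unit_id", "locality", "habitat", "gear", "campaign_date",
           "campaign", "season", "time", "area_m2")
  per_origin <- survey$catches %>%
    filter(.data$n_individuals > 0) %>%
    inner_join(survey$registry[c("species_id", "origin")], by = "species_id") %>%
    filter(.data$origin != "unclassified") %>%
    inner_join(keys[c("unit_id", "area_m2")], by = "unit_id") %>%
    group_by(.data$unit_id, .data$origin) %>%
    summarise(
      R = n_distinct(.data$species_id),
      B = sum(biomass_density(.data$total_weight_g, .data$area_m2)),
      .groups = "drop"
    ) %>%
    tidyr::pivot_wider(names_from = "origin", values_from = c("R", "B"),
                       values_fill = 0)
  for (col in c("R_native", "R_non_native", "B_native", "B_non_native")) {
    if (!col %in% names(per_origin)) per_origin[[col]] <- 0
  }
  keys %>%
    left_join(per_origin, by = "unit_id") %>%
    mutate(
      R_n = coalesce(.data$R_native, 0),
      R_nn = coalesce(.data$R_non_native, 0),
      B_n = coalesce(.data$B_native, 0),
      B_nn = coalesce(.data$B_non_native, 0),
      R_s = .data$R_n + .data$R_nn,
      B_s = .data$B_n + .data$B_nn
    ) %>%
    select(-"R_native", -"R_non_native", -"B_native", -"B_non_native")
}

#' Summarise a single sampling unit
#'
#' @param survey A validated `survey_table`.
#' @param unit_id Id of an existing sampling unit.
#' @inheritParams summarize_units
#' @return A one-row tibble, see [summarize_units()].
#' @export
summarize_unit <- function(survey, unit_id, check = TRUE) {
  out <- summarize_units(survey, check = check)
  out <- out[out$unit_id == unit_id, ]
  if (nrow(out) == 0) stop("unknown unit_id: ", unit_id, call. = FALSE)
  out
}

#' Contamination indices
#'
#' Computes the five contamination indices from per-unit assemblage
#' summaries.  With native / non-native richness \eqn{R_n, R_{nn}} and
#' biomass densities \eqn{B_n, B_{nn}}:
#'
#' * `CI_r = R_nn / (R_nn + R_n)` -- richness contamination;
#' * `CI_b = B_nn / (B_nn + B_n)` -- biomass contamination;
#' * `CI_e = R_nn B_nn / (R_nn B_nn + R_n B_n)` -- ecosystem contamination,
#'   the richness-by-biomass interaction form;
#' * `CI_a = (CI_b + CI_r) / 2` -- additive (arithmetic-mean) form;
#' * `CI_sq` -- multiplicative form, by default the geometric mean
#'   `sqrt(CI_b * CI_r)` (see `ci_sq_form`).
#'
#' An index whose denominator is zero (e.g. an empty sampling unit) is
#' undefined and returned as `NA`; undefined values are excluded from group
#' averages rather than coerced to 0 or 1, which would bias contamination
#' means.  All defined values lie in \[0, 1\], and `CI_sq <= CI_a` by the
#' AM-GM inequality.
#'
#' @param summaries A tibble with columns `R_n`, `R_nn`, `B_n`, `B_nn`
#'   (e.g. from [summarize_units()]).
#' @param ci_sq_form Form of the multiplicative index: `"geometric"`
#'   (default) for `sqrt(CI_b * CI_r)`, or `"product"` for the plain product
#'   `CI_b * CI_r`.  The geometric mean is the form consistent with
#'   published locality-average index tables for the upper Parana
#'   floodplain; see the package vignette.
#' @return The input tibble with columns `CI_r`, `CI_b`, `CI_e`, `CI_a`,
#'   `CI_sq` appended.
#' @export
contamination_indices <- function(summaries,
                                  ci_sq_form = c("geometric", "product")) {
  ci_sq_form <- match.arg(ci_sq_form)
  need <- c("R_n", "R_nn", "B_n", "B_nn")
  if (!all(need %in% names(summaries))) {
    stop("summaries must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  summaries %>%
    mutate(
      CI_r = ratio(.data$R_nn, .data$R_nn + .data$R_n),
      CI_b = ratio(.data$B_nn, .data$B_nn + .data$B_n),
      CI_e = ratio(.data$R_nn * .data$B_nn,
                   .data$R_nn * .data$B_nn + .data$R_n * .data$B_n),
      CI_a = ci_additive(.data$CI_b, .data$CI_r),
      CI_sq = ci_multiplicative(.data$CI_b, .data$CI_r, form = ci_sq_form)
    )
}

#' Additive and multiplicative index forms
#'
#' The additive and multiplicative contamination indices are pure functions
#' of the biomass and richness indices, so they apply equally to per-unit
#' values and to locality averages: the additive form is linear, hence the
#' mean `CI_a` of a group equals `ci_additive(mean CI_b, mean CI_r)` exactly.
#'
#' @param ci_b,ci_r Biomass and richness contamination values (or means).
#' @param form `"geometric"` for `sqrt(ci_b * ci_r)`, `"product"` for
#'   `ci_b * ci_r`.
#' @return Numeric vector of index values; `NA` where either input is `NA`.
#' @examples
#' ci_additive(0.61, 0.55)              # locality-average additive index
#' ci_multiplicative(0.64, 0.55)        # geometric-mean form
#' @export
ci_additive <- function(ci_b, ci_r) {
  (ci_b + ci_r) / 2
}

#' @rdname ci_additive
#' @export
ci_multiplicative <- function(ci_b, ci_r, form = c("geometric", "product")) {
  form <- match.arg(form)
  if (form == "geometric") sqrt(ci_b * ci_r) else ci_b * ci_r
}
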