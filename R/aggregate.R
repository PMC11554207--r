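#' Aggregate unit-level metrics into locality or campaign series
#'
#' Averages per-unit biomass, richness and contamination indices either per
#' locality (for temporal summaries) or per campaign (for spatial
#' summaries), optionally split by gear, and attaches the two higher-level
#' statistics:
#'
#' * `rho`, `rho_p`: Spearman correlation between per-unit biomass and
#'   species richness across the group's sampling units, per origin class
#'   (see [spearman_rho()]);
#' * `Q`: Kempton's Q per origin class, computed on the per-species biomass
#'   distribution of each (locality, campaign) cell in the group and
#'   averaged over the group's cells, skipping undefined cells (see
#'   [kempton_q_campaign()]).  By default gears are pooled when forming the
#'   per-species biomass distributions, since sampling method was not found
#'   to drive the variability of these summaries; set `pool_gears_q =
#'   FALSE` to compute Q within gear.
#'
#' Contamination indices are computed per sampling unit and then averaged
#' (undefined units excluded), so `mean CI_a = (mean CI_b + mean CI_r) / 2`
#' holds exactly by linearity.  Standard deviations are reported only for
#' groups with at least two defined values.
#'
#' @param survey A validated `survey_table`.
#' @param by Grouping dimension: `"locality"` or `"campaign"`.
#' @param gear_split Split groups by gear (default `TRUE`).
#' @param ci_sq_form Passed to [contamination_indices()].
#' @param pool_gears_q Pool gears when computing Q (default `TRUE`).
#' @return A tibble with one row per group and origin class: keys
#'   (`locality`, `campaign`, `gear`, `origin`; unused key is `NA`),
#'   `n_units`, `mean_biomass`, `sd_biomass`, `mean_richness`,
#'   `sd_richness`, the five mean indices (`CIe`, `CIb`, `CIa`, `CIsq`,
#'   `CIr`), `rho`, `rho_p`, and `Q`.
#' @export
aggregate_series <- function(survey, by = c("locality", "campaign"),
                             gear_split = TRUE,
                             ci_sq_form = c("geometric", "product"),
                             pool_gears_q = TRUE) {
  by <- match.arg(by)
  ci_sq_form <- match.arg(ci_sq_form)
  us <- contamination_indices(summarize_units(survey), ci_sq_form)
  keys <- c(by, if (gear_split) "gear")

  sd_if <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) >= 2) sd(x) else NA_real_
  }
  mean_if <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 0) mean(x) else NA_real_
  }
  rho_of <- function(b, r) {
    if (length(b) < 3) return(c(NA_real_, NA_real_))
    s <- spearman_rho(b, r)
    c(s$rho, s$p)
  }

  per_origin <- purrr::map_dfr(c("native", "non_native"), function(org) {
    bcol <- if (org == "native") "B_n" else "B_nn"
    rcol <- if (org == "native") "R_n" else "R_nn"
    us %>%
      group_by(across(all_of(keys))) %>%
      summarise(
        origin = org,
        n_units = n(),
        mean_biomass = mean(.data[[bcol]]),
        sd_biomass = sd_if(.data[[bcol]]),
        mean_richness = mean(.data[[rcol]]),
        sd_richness = sd_if(.data[[rcol]]),
        CIe = mean_if(.data$CI_e),
        CIb = mean_if(.data$CI_b),
        CIa = mean_if(.data$CI_a),
        CIsq = mean_if(.data$CI_sq),
        CIr = mean_if(.data$CI_r),
        rho = rho_of(.data[[bcol]], .data[[rcol]])[1],
        rho_p = rho_of(.data[[bcol]], .data[[rcol]])[2],
        .groups = "drop"
      )
  })

  qtab <- kempton_by_group(survey, keys = keys, pool_gears = pool_gears_q)
  out <- per_origin %>%
    left_join(qtab, by = c(keys, "origin"))
  if (!"locality" %in% names(out)) out$locality <- NA_character_
  if (!"campaign" %in% names(out)) out$campaign <- NA_character_
  if (!"gear" %in% names(out)) out$gear <- NA_character_
  out %>%
    select("locality", "campaign", "gear", "origin", "n_units",
           "mean_biomass", "sd_biomass", "mean_richness", "sd_richness",
           "CIe", "CIb", "CIa", "CIsq", "CIr", "rho", "rho_p", "Q") %>%
    arrange(across(any_of(c("campaign", "locality", "gear", "origin"))))
}

# Per-species biomass density per (locality, campaign[, gear]) cell and
# origin class: summed species weight over the cell's units divided by the
# cell's total sampled area.
species_biomass_cells <- function(survey, pool_gears = TRUE) {
  cell_keys <- c("locality", "campaign", if (!pool_gears) "gear")
  units <- survey$units %>%
    select("unit_id", all_of(cell_keys), "area_m2")
  cell_area <- units %>%
    group_by(across(all_of(cell_keys))) %>%
    summarise(cell_area_m2 = sum(.data$area_m2), .groups = "drop")
  survey$catches %>%
    filter(.data$n_individuals > 0) %>%
    inner_join(survey$registry[c("species_id", "origin")],
               by = "species_id") %>%
    filter(.data$origin != "unclassified") %>%
    inner_join(units, by = "unit_id") %>%
    group_by(across(all_of(cell_keys)), .data$origin, .data$species_id) %>%
    summarise(weight_g = sum(.data$total_weight_g), .groups = "drop") %>%
    inner_join(cell_area, by = cell_keys) %>%
    mutate(B = .data$weight_g / .data$cell_area_m2)
}

# Mean Kempton's Q per group x origin, averaging per-cell Q values.
kempton_by_group <- function(survey, keys, pool_gears = TRUE) {
  cells <- species_biomass_cells(survey, pool_gears = pool_gears)
  cell_keys <- c("locality", "campaign", if (!pool_gears) "gear")
  q_cells <- cells %>%
    group_by(across(all_of(cell_keys)), .data$origin) %>%
    summarise(q = kempton_q(.data$B), .groups = "drop")
  if (pool_gears && "gear" %in% keys) {
    # pooled-gear Q is attached identically to each gear stratum
    gears <- unique(survey$units$gear)
    q_cells <- tidyr::crossing(q_cells, gear = gears)
  }
  group_keys <- intersect(c(keys, "origin"), names(q_cells))
  q_cells %>%
    group_by(across(all_of(group_keys))) %>%
    summarise(
      Q = if (any(!is.na(.data$q))) mean(.data$q[!is.na(.data$q)]) else NA_real_,
      .groups = "drop"
    )
}
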