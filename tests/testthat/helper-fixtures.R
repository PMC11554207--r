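library(dplyr)

# Hand-built fixtures, constructed in code at test time.

# A minimal registry: two natives, one non-native, one unclassified.
tiny_registry <- function() {
  tibble::tibble(
    species_id = c("nat1", "nat2", "inv1", "unk1"),
    species_name = c("Astyanax paranensis", "Pimelodus maculatus",
                     "Cichla synthetic", "Incertae sedis"),
    origin = c("native", "native", "non_native", "unclassified")
  )
}

# Three sampling units: a gillnet unit with known hand-computed biomass
# (native weights 200 + 100 g, non-native 68 g over 368 m^2), an empty
# seine unit, and a river gillnet unit.
tiny_survey <- function() {
  units <- tibble::tibble(
    unit_id = c("u1", "u2", "u3"),
    locality = c("lgar", "lgar", "rbai"),
    habitat = c("lake", "lake", "river"),
    gear = c("gillnet", "seine", "gillnet"),
    campaign_date = as.Date(c("2003-05-15", "2003-05-20", "2003-08-15")),
    area_m2 = c(368, 247.69, 368)
  )
  catches <- tibble::tibble(
    unit_id = c("u1", "u1", "u1", "u1", "u3"),
    species_id = c("nat1", "nat2", "inv1", "unk1", "nat1"),
    n_individuals = c(4, 2, 1, 3, 5),
    total_weight_g = c(200, 100, 68, 50, 500)
  )
  survey_table(units, catches, tiny_registry())
}

# A randomized valid survey for round-trip and property tests.
random_survey <- function(seed, n_units = 10, n_species = 8) {
  set.seed(seed)
  registry <- tibble::tibble(
    species_id = sprintf("sp%02d", seq_len(n_species)),
    species_name = sprintf("Genus species%02d", seq_len(n_species)),
    origin = sample(c("native", "non_native", "unclassified"), n_species,
                    replace = TRUE, prob = c(0.5, 0.4, 0.1))
  )
  locs <- c("lfec", "lgar", "rbai", "rivi")
  loc <- sample(locs, n_units, replace = TRUE)
  habitat <- ifelse(startsWith(loc, "l"), "lake", "river")
  gear <- ifelse(habitat == "lake",
                 sample(c("gillnet", "seine"), n_units, replace = TRUE),
                 "gillnet")
  units <- tibble::tibble(
    unit_id = sprintf("u%03d", seq_len(n_units)),
    locality = loc, habitat = habitat, gear = gear,
    campaign_date = as.Date("2000-02-15") + sample(0:6000, n_units),
    area_m2 = round(runif(n_units, 30, 400), 2)
  )
  catches <- tidyr::crossing(unit_id = units$unit_id,
                             species_id = registry$species_id) %>%
    dplyr::slice_sample(prop = 0.5) %>%
    dplyr::mutate(
      n_individuals = rpois(dplyr::n(), 4) + 1,
      total_weight_g = round(n_individuals * runif(dplyr::n(), 5, 300), 3)
    )
  survey_table(units, catches, registry)
}

# Small simulation config for fast mechanism tests.
small_config <- function(seed = 1, ...) {
  cfg <- default_config(seed = seed)
  cfg$start_year <- 2000
  cfg$end_year <- 2007
  cfg$n_lakes <- 3
  cfg$n_rivers <- 1
  mods <- list(...)
  for (nm in names(mods)) cfg[[nm]] <- mods[[nm]]
  cfg
}

# Type-7 quantile computed from first principles (independent of
# stats::quantile): linear interpolation between order statistics.
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Independent enumeration oracle: walks all 2^n subsets by bitmask and
# keeps those of size n1 (no combn, unlike the implementation).
oracle_wilcoxon <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  n <- n1 + n2
  r <- rank(pooled)
  offset <- n1 * (n1 + 1) / 2
  u_obs <- sum(r[seq_len(n1)]) - offset
  mu <- n1 * n2 / 2
  u_all <- numeric(0)
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) != n1) next
    u_all <- c(u_all, sum(r[idx]) - offset)
  }
  list(u = u_obs, p = mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}
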