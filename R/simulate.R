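#' Default simulation configuration
#'
#' Returns the configuration of the synthetic floodplain survey generator,
#' with defaults emulating the upper Parana floodplain long-term monitoring
#' design: 9 localities (6 lakes, 3 river channels), quarterly campaigns
#' 2000--2017, fixed 368 m^2 gillnetting effort in lakes and rivers, beach
#' seining in lakes from 2003 with sampled areas around 247.69 +/- 51.52
#' m^2 (truncated to the observed 30.2--367.09 m^2 range), a regional pool
#' of 42 native and 26 non-native species, a lognormal species-abundance
#' distribution, lognormal body masses driving gear size selectivity, and a
#' non-native colonization process that accelerates through time and is
#' boosted in the flood-pulse years 2010, 2011, 2015 and 2016.  Gillnetting
#' is skipped in the first (high-water) quarter of each flood year, giving
#' 68 gillnet campaigns against 60 seine campaigns.
#'
#' Native local extinction is invasion-driven: each successful non-native
#' establishment extirpates the rarest resident native with probability
#' `native_extinction_rate`, so with colonization switched off the
#' community is stationary (a true null for trend calibration).
#'
#' @param seed Integer RNG seed stored in the configuration.
#' @return A list of class `sim_config`.  Fields and defaults:
#' \describe{
#'   \item{n_lakes, n_rivers}{6 and 3 localities.}
#'   \item{start_year, end_year, campaigns_per_year}{2000, 2017, 4.}
#'   \item{gillnet_area_m2}{368.}
#'   \item{seine_area_mean_m2, seine_area_sd_m2}{247.69, 51.52.}
#'   \item{seine_area_min_m2, seine_area_max_m2}{30.2, 367.09.}
#'   \item{seine_start_year}{2003.}
#'   \item{skip_flood_peak_gillnetting}{`TRUE` (drops Q1 of flood years).}
#'   \item{initial_native_pool, initial_nonnative_pool}{42, 26.}
#'   \item{init_native_occupancy, init_nonnative_occupancy}{0.85, 0.35:
#'     probability a pool species starts resident in a locality.}
#'   \item{sad_lognormal_mu, sad_lognormal_sigma}{log(0.05), 1: lognormal
#'     species-abundance distribution of regional mean densities
#'     (individuals per m^2).}
#'   \item{body_mass_lognormal_mu, body_mass_lognormal_sigma}{log(40), 1:
#'     per-species body mass (g).}
#'   \item{weight_noise_sdlog}{0.1: lognormal noise on emitted weights.}
#'   \item{nb_dispersion}{2: negative-binomial size of per-species counts.}
#'   \item{colonization_rate_per_campaign}{0.01 baseline establishment
#'     probability per absent non-native per locality per campaign.}
#'   \item{colonization_acceleration}{1.08 multiplicative yearly increase.}
#'   \item{flood_years, flood_multiplier}{2010/2011/2015/2016, 4.}
#'   \item{native_extinction_rate}{0.25 per establishment (see above).}
#'   \item{gillnet_selectivity}{0.3: gillnets retain species above this
#'     body-mass quantile of the pool.}
#'   \item{seine_selectivity}{0.7: seines retain species below this
#'     quantile.}
#'   \item{perfect_detection}{`FALSE`; `TRUE` disables selectivity and
#'     guarantees every resident species is caught (observation-error-free
#'     limit for recovery checks).}
#'   \item{seed}{RNG seed.}
#' }
#' @export
default_config <- function(seed = 1) {
  structure(list(
    n_lakes = 6, n_rivers = 3,
    start_year = 2000, end_year = 2017, campaigns_per_year = 4,
    gillnet_area_m2 = 368,
    seine_area_mean_m2 = 247.69, seine_area_sd_m2 = 51.52,
    seine_area_min_m2 = 30.2, seine_area_max_m2 = 367.09,
    seine_start_year = 2003,
    skip_flood_peak_gillnetting = TRUE,
    initial_native_pool = 42, initial_nonnative_pool = 26,
    init_native_occupancy = 0.85, init_nonnative_occupancy = 0.35,
    sad_lognormal_mu = log(0.05), sad_lognormal_sigma = 1,
    body_mass_lognormal_mu = log(40), body_mass_lognormal_sigma = 1,
    weight_noise_sdlog = 0.1,
    nb_dispersion = 2,
    colonization_rate_per_campaign = 0.01,
    colonization_acceleration = 1.08,
    flood_years = c(2010, 2011, 2015, 2016),
    flood_multiplier = 4,
    native_extinction_rate = 0.25,
    gillnet_selectivity = 0.3,
    seine_selectivity = 0.7,
    perfect_detection = FALSE,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

validate_sim_config <- function(config) {
  c <- config
  ok <- function(cond, msg) if (!cond) stop("invalid config: ", msg,
                                            call. = FALSE)
  rates <- c("init_native_occupancy", "init_nonnative_occupancy",
             "colonization_rate_per_campaign", "native_extinction_rate",
             "gillnet_selectivity", "seine_selectivity")
  for (r in rates) ok(c[[r]] >= 0 && c[[r]] <= 1,
                     paste(r, "must be in [0, 1]"))
  ok(c$initial_native_pool >= 1, "initial_native_pool must be >= 1")
  ok(c$initial_nonnative_pool >= 0, "initial_nonnative_pool must be >= 0")
  ok(c$flood_multiplier >= 1, "flood_multiplier must be >= 1")
  ok(c$colonization_acceleration > 0,
     "colonization_acceleration must be > 0")
  ok(c$n_lakes >= 1 && c$n_rivers >= 0, "need at least one lake")
  ok(c$gillnet_area_m2 > 0 && c$seine_area_mean_m2 > 0, "areas must be > 0")
  ok(c$campaigns_per_year %in% 1:4, "campaigns_per_year must be 1..4")
  ok(c$end_year >= c$start_year, "end_year must be >= start_year")
  ok(c$nb_dispersion > 0, "nb_dispersion must be > 0")
  invisible(config)
}

locality_codes <- function(n_lakes, n_rivers) {
  canonical_lakes <- c("lfec", "lgar", "lgua", "lpat", "lpve", "lven")
  canonical_rivers <- c("rbai", "rivi", "rpar")
  lakes <- if (n_lakes <= 6) canonical_lakes[seq_len(n_lakes)] else
    c(canonical_lakes, sprintf("l%02d", seq_len(n_lakes - 6)))
  rivers <- if (n_rivers <= 3) canonical_rivers[seq_len(n_rivers)] else
    c(canonical_rivers, sprintf("r%02d", seq_len(n_rivers - 3)))
  list(lakes = lakes, rivers = rivers)
}

#' Simulate a floodplain fish survey
#'
#' Generates a synthetic survey with the statistical structure the analysis
#' assumes.  Mechanism: (i) each pool species receives a regional mean
#' density from the lognormal species-abundance distribution and a body
#' mass from the body-mass lognormal; (ii) each locality starts with a
#' random subset of the native pool and a smaller subset of non-natives;
#' (iii) each campaign, each absent non-native establishes in a locality
#' with probability `colonization_rate_per_campaign *
#' colonization_acceleration^(years elapsed)`, multiplied by
#' `flood_multiplier` in flood years; river localities are processed before
#' lakes (rivers are the dispersal corridor); (iv) each establishment may
#' extirpate the rarest resident native (probability
#' `native_extinction_rate`); (v) each sampling event draws per-species
#' counts as negative binomial around local density times sampled area,
#' after gear size selectivity on body mass (gillnets retain large species,
#' seines small ones); emitted weight is count times body mass times
#' lognormal noise; (vi) the result is a valid [survey_table()] plus the
#' realized true state.  The same configuration and seed always produce
#' identical output; the caller's RNG state is left untouched.
#'
#' @param config A `sim_config`, see [default_config()].
#' @return A list of class `sim_survey`: `survey` (a `survey_table`),
#'   `truth` (tibble with one row per locality and campaign:
#'   `locality`, `campaign`, `year`, `time`, `n_native_resident`,
#'   `n_nonnative_resident`, `frac_nonnative`, `n_colonizations`,
#'   `n_extinctions`), and `config`.
#' @export
simulate_survey <- function(config = default_config()) {
  validate_sim_config(config)
  with_seed(config$seed, simulate_survey_impl(config))
}

simulate_survey_impl <- function(cfg) {
  locs <- locality_codes(cfg$n_lakes, cfg$n_rivers)
  localities <- c(locs$rivers, locs$lakes)  # rivers first: dispersal corridor
  habitat <- setNames(
    c(rep("river", length(locs$rivers)), rep("lake", length(locs$lakes))),
    localities)

  n_n <- cfg$initial_native_pool
  n_nn <- cfg$initial_nonnative_pool
  n_sp <- n_n + n_nn
  registry <- synthetic_species_registry(n_native = n_n, n_nonnative = n_nn,
                                         n_unclassified = 0)
  origin <- registry$origin
  lambda <- rlnorm(n_sp, cfg$sad_lognormal_mu, cfg$sad_lognormal_sigma)
  mass <- rlnorm(n_sp, cfg$body_mass_lognormal_mu,
                 cfg$body_mass_lognormal_sigma)
  if (cfg$perfect_detection) {
    gill_keep <- seine_keep <- rep(TRUE, n_sp)
  } else {
    gill_keep <- mass >= quantile(mass, cfg$gillnet_selectivity, type = 7)
    seine_keep <- mass <= quantile(mass, cfg$seine_selectivity, type = 7)
  }

  months <- c(2, 5, 8, 11)[seq_len(cfg$campaigns_per_year)]
  cal <- tidyr::crossing(year = cfg$start_year:cfg$end_year,
                         q = seq_along(months)) %>%
    mutate(
      month = months[.data$q],
      date = as.Date(sprintf("%04d-%02d-15", .data$year, .data$month)),
      flood = .data$year %in% cfg$flood_years,
      gillnet = !(cfg$skip_flood_peak_gillnetting & .data$flood &
                    .data$q == 1),
      seine = .data$year >= cfg$seine_start_year
    ) %>%
    arrange(.data$date)
  n_camp <- nrow(cal)

  loc_seed <- sample.int(2147483646L, length(localities))
  native_idx <- which(origin == "native")
  nonnative_idx <- which(origin == "non_native")

  truth_rows <- vector("list", length(localities))
  unit_rows <- vector("list", length(localities))
  catch_rows <- vector("list", length(localities))

  for (li in seq_along(localities)) {
    loc <- localities[li]
    set.seed(loc_seed[li])
    present <- logical(n_sp)
    present[native_idx] <- runif(n_n) < cfg$init_native_occupancy
    present[nonnative_idx] <- runif(max(n_nn, 0)) < cfg$init_nonnative_occupancy

    presence <- matrix(FALSE, n_camp, n_sp)
    n_col <- n_ext <- integer(n_camp)
    for (ci in seq_len(n_camp)) {
      elapsed <- cal$year[ci] - cfg$start_year
      p_col <- min(1, cfg$colonization_rate_per_campaign *
                     cfg$colonization_acceleration^elapsed *
                     if (cal$flood[ci]) cfg$flood_multiplier else 1)
      absent_nn <- nonnative_idx[!present[nonnative_idx]]
      if (length(absent_nn) > 0 && p_col > 0) {
        arrive <- absent_nn[runif(length(absent_nn)) < p_col]
        present[arrive] <- TRUE
        n_col[ci] <- length(arrive)
        for (a in seq_along(arrive)) {
          res_nat <- native_idx[present[native_idx]]
          if (length(res_nat) > 0 &&
              runif(1) < cfg$native_extinction_rate) {
            rarest <- res_nat[which.min(lambda[res_nat])]
            present[rarest] <- FALSE
            n_ext[ci] <- n_ext[ci] + 1L
          }
        }
      }
      presence[ci, ] <- present
    }

    truth_rows[[li]] <- tibble(
      locality = loc,
      campaign = campaign_of(cal$date),
      year = cal$year,
      n_native_resident = rowSums(presence[, native_idx, drop = FALSE]),
      n_nonnative_resident = rowSums(presence[, nonnative_idx,
                                              drop = FALSE]),
      n_colonizations = n_col,
      n_extinctions = n_ext
    ) %>%
      mutate(frac_nonnative = .data$n_nonnative_resident /
               (.data$n_nonnative_resident + .data$n_native_resident))

    gears <- c("gillnet", if (habitat[loc] == "lake") "seine")
    uu <- list()
    cc <- list()
    for (gear in gears) {
      camp_idx <- which(if (gear == "gillnet") cal$gillnet else cal$seine)
      keep <- if (gear == "gillnet") gill_keep else seine_keep
      area <- if (gear == "gillnet") {
        rep(cfg$gillnet_area_m2, length(camp_idx))
      } else {
        pmin(pmax(rnorm(length(camp_idx), cfg$seine_area_mean_m2,
                        cfg$seine_area_sd_m2),
                  cfg$seine_area_min_m2), cfg$seine_area_max_m2)
      }
      uid <- sprintf("%s-%04dQ%d-%s", loc, cal$year[camp_idx],
                     cal$q[camp_idx], substr(gear, 1, 3))
      uu[[gear]] <- tibble(
        unit_id = uid, locality = loc, habitat = unname(habitat[loc]),
        gear = gear, campaign_date = cal$date[camp_idx], area_m2 = area)

      avail <- presence[camp_idx, , drop = FALSE] &
        matrix(keep, length(camp_idx), n_sp, byrow = TRUE)
      hit <- which(avail, arr.ind = TRUE)  # (sampling event, species)
      if (nrow(hit) == 0) next
      hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
      mu <- lambda[hit[, 2]] * area[hit[, 1]]
      count <- if (cfg$perfect_detection) {
        pmax(1, ceiling(mu))
      } else {
        rnbinom(length(mu), mu = mu, size = cfg$nb_dispersion)
      }
      caught <- count > 0
      if (!any(caught)) next
      hit <- hit[caught, , drop = FALSE]
      count <- count[caught]
      w <- count * mass[hit[, 2]] *
        exp(rnorm(length(count), 0, cfg$weight_noise_sdlog))
      cc[[gear]] <- tibble(
        unit_id = uid[hit[, 1]], species_id = registry$species_id[hit[, 2]],
        n_individuals = as.numeric(count), total_weight_g = w)
    }
    unit_rows[[li]] <- bind_rows(uu)
    catch_rows[[li]] <- bind_rows(cc)
  }

  units <- bind_rows(unit_rows) %>% arrange(.data$unit_id)
  catches <- bind_rows(catch_rows) %>%
    arrange(.data$unit_id, .data$species_id)
  truth <- bind_rows(truth_rows) %>%
    mutate(time = years_since(as.Date(paste0(
      substr(.data$campaign, 1, 4), "-",
      sprintf("%02d", as.integer(substr(.data$campaign, 7, 7)) * 3 - 1),
      "-15"))))

  structure(
    list(survey = survey_table(units, catches, registry), truth = truth,
         config = cfg),
    class = "sim_survey"
  )
}

#' @export
print.sim_survey <- function(x, ...) {
  cat("<sim_survey> seed", x$config$seed, "\n")
  print(x$survey)
  invisible(x)
}
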