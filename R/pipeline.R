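#' Read and write simulation configurations
#'
#' The simulator configuration round-trips through a flat `key: value` text
#' file whose keys are exactly the [default_config()] field names;
#' `flood_years` is a comma-separated list.  Unknown keys are an error.
#'
#' @param path Path of the configuration file.
#' @param config A `sim_config`.
#' @return `read_sim_config()` returns a `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  template <- default_config()
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  out <- template
  for (line in lines) {
    kv <- strsplit(line, ":", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    if (!key %in% names(template)) {
      stop("unknown config key: ", key, call. = FALSE)
    }
    proto <- template[[key]]
    out[[key]] <- if (is.logical(proto)) {
      as.logical(val)
    } else if (key == "flood_years") {
      as.numeric(trimws(strsplit(val, ",")[[1]]))
    } else if (is.integer(proto)) {
      as.integer(val)
    } else {
      as.numeric(val)
    }
  }
  class(out) <- "sim_config"
  validate_sim_config(out)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  lines <- vapply(names(config), function(nm) {
    sprintf("%s: %s", nm,
            paste(format(config[[nm]], digits = 17, scientific = FALSE),
                  collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Deterministic run manifest: stage entries with md5 digests of the files
# each stage wrote, so every output table is traceable to a seed and
# configuration.  No timestamps: pipeline outputs are byte-reproducible.
write_manifest <- function(out_dir, stage, files, seed = NULL,
                           extra = list()) {
  path <- file.path(out_dir, "manifest.json")
  manifest <- if (file.exists(path)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    list(package = "floodcontam",
         version = as.character(utils::packageVersion("floodcontam")))
  }
  digests <- tools::md5sum(files)
  names(digests) <- basename(names(digests))
  entry <- c(list(files = as.list(digests)), extra)
  if (!is.null(seed)) entry$seed <- seed
  manifest[[stage]] <- entry
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

resolve_survey <- function(input) {
  if (inherits(input, "sim_survey")) return(input$survey)
  if (inherits(input, "survey_table")) return(input)
  if (is.character(input) && dir.exists(input)) {
    return(read_survey(file.path(input, "units.csv"),
                       file.path(input, "catches.csv"),
                       file.path(input, "registry.csv")))
  }
  stop("input must be a survey_table, sim_survey, or a directory of CSVs",
       call. = FALSE)
}

#' Simulate a survey and write its files
#'
#' Runs [simulate_survey()] and writes `units.csv`, `catches.csv`,
#' `registry.csv`, `truth.csv`, the flat `config.txt`, and a `manifest.json`
#' recording the seed, the configuration digest, and per-file digests.
#' Identical configuration and seed produce byte-identical files.
#'
#' @param config A `sim_config` (default [default_config()]).
#' @param out_dir Output directory, created if missing.
#' @param seed Optional seed overriding `config$seed`.
#' @return Invisibly, the `sim_survey` object.
#' @export
run_simulate <- function(config = default_config(), out_dir, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory ", out_dir)
  }
  sim <- simulate_survey(config)
  paths <- write_survey(sim$survey, out_dir)
  truth_path <- file.path(out_dir, "truth.csv")
  readr::write_csv(sim$truth, truth_path, progress = FALSE)
  cfg_path <- file.path(out_dir, "config.txt")
  write_sim_config(config, cfg_path)
  write_manifest(
    out_dir, "simulate", c(paths, truth = truth_path),
    seed = config$seed,
    extra = list(config_hash = unname(tools::md5sum(cfg_path)))
  )
  message(sprintf("simulate: %d units, %d catches, %d species (seed %d)",
                  nrow(sim$survey$units), nrow(sim$survey$catches),
                  nrow(sim$survey$registry), config$seed))
  invisible(sim)
}

#' Compute and write metric tables
#'
#' Validates the survey (aborting with the printed report on errors) and
#' writes two report tables: `metrics_locality.csv` (locality-by-gear
#' averages of biomass, richness and the five contamination indices, with
#' rho and Kempton's Q -- the spatial summary) and `metrics_campaign.csv`
#' (the same summaries per campaign -- the temporal series).  Undefined
#' values are written as empty cells, never as 0.  Values are rounded to
#' `digits` decimals half-away-from-zero to match report-table conventions;
#' pass `digits = NULL` for full precision.
#'
#' @param input A `survey_table`, `sim_survey`, or directory containing the
#'   survey CSVs.
#' @param out_dir Output directory.
#' @param ci_sq_form Passed to [contamination_indices()].
#' @param digits Decimal places for the written tables (default 2).
#' @return Invisibly, a list with the two (unrounded) tibbles.
#' @export
run_metrics <- function(input, out_dir, ci_sq_form = "geometric",
                        digits = 2) {
  survey <- resolve_survey(input)
  assert_valid(survey)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  by_loc <- aggregate_series(survey, by = "locality",
                             ci_sq_form = ci_sq_form)
  by_camp <- aggregate_series(survey, by = "campaign", gear_split = FALSE,
                              ci_sq_form = ci_sq_form)
  rounded <- function(x) {
    if (is.null(digits)) return(x)
    mutate(x, across(where(is.numeric) & !any_of("n_units"),
                     ~ round_half_away(.x, digits)))
  }
  p1 <- file.path(out_dir, "metrics_locality.csv")
  p2 <- file.path(out_dir, "metrics_campaign.csv")
  readr::write_csv(rounded(by_loc), p1, na = "", progress = FALSE)
  readr::write_csv(rounded(by_camp), p2, na = "", progress = FALSE)
  write_manifest(out_dir, "metrics", c(p1, p2))
  message(sprintf("metrics: %d locality rows, %d campaign rows",
                  nrow(by_loc), nrow(by_camp)))
  invisible(list(locality = by_loc, campaign = by_camp))
}

# Numeric mid-quarter time axis for campaign labels ("YYYY-Qq").
campaign_time <- function(campaign) {
  year <- as.integer(substr(campaign, 1, 4))
  q <- as.integer(substr(campaign, 7, 7))
  year + (q - 0.5) / 4
}

#' Fit and write temporal trend tables
#'
#' Runs the trend layer over a survey: per gear and origin, penalized-smooth
#' fits of per-unit biomass and species richness against time with locality
#' random intercepts and AR(1) errors (seine biomass is log10(x+1)
#' transformed); per gear, the same fits for each per-unit contamination
#' index; and single-series fits of the per-campaign Kempton's Q and
#' biomass-richness rho per origin class (gears pooled).  Writes
#' `trends.csv` (`method,origin,response,beta,beta_sd,edf,ref_df,F,p,
#' adj_R2,phi`) and `comparison.csv` (Mann-Whitney comparisons of the rho
#' distributions between origins, with and without 1.5-IQR outlier
#' removal).  Groups with too few observations are skipped with a warning.
#'
#' @inheritParams run_metrics
#' @param k Spline basis dimension passed to [fit_smooth_trend()].
#' @return Invisibly, a list with `trends`, `comparisons`, and the named
#'   list of `trend_fit` objects.
#' @export
run_trends <- function(input, out_dir, ci_sq_form = "geometric", k = 10) {
  survey <- resolve_survey(input)
  assert_valid(survey)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  us <- contamination_indices(summarize_units(survey, check = FALSE),
                              ci_sq_form = ci_sq_form)

  fits <- list()
  rows <- list()
  add_fit <- function(label, method, origin, response, time, y, locality,
                      transform = "none") {
    ok <- is.finite(y) & is.finite(time)
    if (sum(ok) < 10) {
      warning("skipping ", label, ": fewer than 10 observations",
              call. = FALSE)
      return(NULL)
    }
    fit <- fit_smooth_trend(time[ok], y[ok],
                            locality = if (is.null(locality)) NULL else
                              locality[ok],
                            transform = transform, k = k, label = label)
    fits[[label]] <<- fit
    rows[[label]] <<- tibble(
      method = method, origin = origin, response = response,
      beta = fit$beta, beta_sd = fit$beta_sd, edf = fit$edf,
      ref_df = fit$ref_df, F = fit$F, p = fit$p, adj_R2 = fit$adj_r2,
      phi = fit$phi)
  }

  for (gear in sort(unique(us$gear))) {
    ug <- us[us$gear == gear, ]
    transform <- if (gear == "seine") "log10p1" else "none"
    for (org in c("native", "non_native")) {
      bcol <- if (org == "native") "B_n" else "B_nn"
      rcol <- if (org == "native") "R_n" else "R_nn"
      add_fit(paste(gear, org, "biomass", sep = "."), gear, org, "biomass",
              ug$time, ug[[bcol]], ug$locality, transform)
      add_fit(paste(gear, org, "richness", sep = "."), gear, org,
              "richness", ug$time, ug[[rcol]], ug$locality)
    }
    for (idx in c("CI_e", "CI_b", "CI_a", "CI_sq", "CI_r")) {
      add_fit(paste(gear, idx, sep = "."), gear, NA_character_,
              sub("_", "", idx), ug$time, ug[[idx]], ug$locality)
    }
  }

  by_camp <- aggregate_series(survey, by = "campaign", gear_split = FALSE,
                              ci_sq_form = ci_sq_form)
  by_camp$t <- campaign_time(by_camp$campaign)
  for (org in c("native", "non_native")) {
    oc <- by_camp[by_camp$origin == org, ]
    add_fit(paste("pooled", org, "Q", sep = "."), "pooled", org, "Q",
            oc$t, oc$Q, NULL)
    add_fit(paste("pooled", org, "rho", sep = "."), "pooled", org, "rho",
            oc$t, oc$rho, NULL)
  }

  trends <- bind_rows(rows)

  rho_n <- by_camp$rho[by_camp$origin == "native"]
  rho_nn <- by_camp$rho[by_camp$origin == "non_native"]
  comparisons <- purrr::map_dfr(c(FALSE, TRUE), function(rm) {
    w <- wilcoxon_rank_sum(rho_nn[is.finite(rho_nn)],
                           rho_n[is.finite(rho_n)], remove_outliers = rm)
    tibble(comparison = "rho_nonnative_vs_native_per_campaign",
           outliers_removed = rm, W = w$statistic, p = w$p, n1 = w$n1,
           n2 = w$n2)
  })

  p1 <- file.path(out_dir, "trends.csv")
  p2 <- file.path(out_dir, "comparison.csv")
  readr::write_csv(trends, p1, na = "", progress = FALSE)
  readr::write_csv(comparisons, p2, na = "", progress = FALSE)
  write_manifest(out_dir, "trends", c(p1, p2))
  message(sprintf("trends: %d fits, %d comparisons", nrow(trends),
                  nrow(comparisons)))
  invisible(list(trends = trends, comparisons = comparisons, fits = fits))
}

#' Run the full pipeline
#'
#' [run_simulate()], [run_metrics()] and [run_trends()] in sequence on one
#' output directory.  With a fixed seed the whole output set is
#' byte-identical across runs.
#'
#' @inheritParams run_simulate
#' @inheritParams run_metrics
#' @return Invisibly, a list `sim`, `metrics`, `trends`.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL,
                         ci_sq_form = "geometric") {
  sim <- run_simulate(config, out_dir, seed = seed)
  metrics <- run_metrics(sim, out_dir, ci_sq_form = ci_sq_form)
  trends <- run_trends(sim, out_dir, ci_sq_form = ci_sq_form)
  invisible(list(sim = sim, metrics = metrics, trends = trends))
}
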