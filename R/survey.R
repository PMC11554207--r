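#' Construct a survey table
#'
#' A survey table bundles the three tables of a floodplain fish survey:
#' sampling units (one gillnetting or seining event at one locality and
#' campaign), catch records (one species' pooled catch in one unit), and the
#' species origin registry.  Campaign labels (`"YYYY-Qq"`), meteorological
#' season (quarter), and continuous time (fractional years since the first
#' campaign) are derived from the campaign date on construction.
#'
#' @param units Tibble with columns `unit_id`, `locality`, `habitat`
#'   (`lake`/`river`), `gear` (`gillnet`/`seine`), `campaign_date` (Date),
#'   `area_m2`.
#' @param catches Tibble with columns `unit_id`, `species_id`,
#'   `n_individuals`, `total_weight_g`.
#' @param registry Registry tibble, see [read_registry()].
#' @return An object of class `survey_table`: a list with elements `units`
#'   (augmented with `season`, `campaign`, `time`), `catches`, `registry`.
#' @export
survey_table <- function(units, catches, registry) {
  units <- as_tibble(units)
  units$campaign_date <- as.Date(units$campaign_date)
  units$area_m2 <- as.numeric(units$area_m2)
  units$season <- paste0("Q", quarter_of(units$campaign_date))
  units$campaign <- campaign_of(units$campaign_date)
  units$time <- years_since(units$campaign_date)
  catches <- as_tibble(catches)
  catches$n_individuals <- as.numeric(catches$n_individuals)
  catches$total_weight_g <- as.numeric(catches$total_weight_g)
  structure(
    list(units = units, catches = catches, registry = as_tibble(registry)),
    class = "survey_table"
  )
}

#' @export
print.survey_table <- function(x, ...) {
  cat("<survey_table>\n")
  cat("  units:   ", nrow(x$units), " (",
      length(unique(x$units$locality)), " localities, ",
      length(unique(x$units$campaign)), " campaigns)\n", sep = "")
  cat("  catches: ", nrow(x$catches), "\n", sep = "")
  org <- table(factor(x$registry$origin, levels = origin_levels))
  cat("  registry:", nrow(x$registry), "species (",
      org[["native"]], "native,", org[["non_native"]], "non-native,",
      org[["unclassified"]], "unclassified )\n")
  invisible(x)
}

#' Read a survey from its CSV tables
#'
#' Reads the `units.csv` / `catches.csv` dialects (comma-delimited, header
#' mandatory, ISO-8601 dates, dot decimal) and links them with a species
#' registry into a [survey_table()].  Referential problems (a catch naming an
#' unknown unit or species) are not fatal here: they are collected by
#' [validate_survey()], whose report is attached as attribute `"validation"`.
#' A non-positive sampled area is a hard error, as no biomass density can be
#' formed from it.
#'
#' @param units_path,catches_path Paths to the two CSV files.
#' @param registry A registry tibble or a path to `registry.csv`.
#' @return A `survey_table` with a `"validation"` attribute.
#' @export
read_survey <- function(units_path, catches_path, registry) {
  if (is.character(registry)) registry <- read_registry(registry)
  units <- readr::read_csv(
    units_path,
    col_types = readr::cols(
      unit_id = "c", locality = "c", habitat = "c", gear = "c",
      campaign_date = readr::col_date(), area_m2 = "d"
    ),
    progress = FALSE
  )
  catches <- readr::read_csv(
    catches_path,
    col_types = readr::cols(unit_id = "c", species_id = "c",
                            n_individuals = "d", total_weight_g = "d"),
    progress = FALSE
  )
  if (any(!is.finite(units$area_m2) | units$area_m2 <= 0)) {
    stop("non-positive or missing sampled area in units: ",
         paste(units$unit_id[!is.finite(units$area_m2) | units$area_m2 <= 0],
               collapse = ", "), call. = FALSE)
  }
  survey <- survey_table(units, catches, registry)
  attr(survey, "validation") <- validate_survey(survey)
  survey
}

#' Write a survey to canonical CSV files
#'
#' Writes `units.csv`, `catches.csv` and `registry.csv` in a canonical form:
#' fixed column order, rows sorted by their keys, ISO dates, dot decimals.
#' Reading the files back with [read_survey()] and writing again reproduces
#' byte-identical files, so the CSV dialect round-trips losslessly.
#'
#' @param survey A `survey_table`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of the three file paths.
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "survey_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  units <- survey$units %>%
    select("unit_id", "locality", "habitat", "gear", "campaign_date",
           "area_m2") %>%
    arrange(.data$unit_id)
  catches <- survey$catches %>%
    select("unit_id", "species_id", "n_individuals", "total_weight_g") %>%
    arrange(.data$unit_id, .data$species_id)
  registry <- survey$registry %>%
    select("species_id", "species_name", "origin") %>%
    arrange(.data$species_id)
  paths <- c(units = file.path(dir, "units.csv"),
             catches = file.path(dir, "catches.csv"),
             registry = file.path(dir, "registry.csv"))
  readr::write_csv(units, paths[["units"]], progress = FALSE)
  readr::write_csv(catches, paths[["catches"]], progress = FALSE)
  readr::write_csv(registry, paths[["registry"]], progress = FALSE)
  invisible(paths)
}
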