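#' Validate a survey table
#'
#' Applies every structural rule of the survey data model and returns a
#' report rather than raising: validation is total on parsable input, and
#' each offending row appears exactly once per violated rule.  Rules:
#'
#' * `unit_id_unique`: unit ids are unique;
#' * `area_positive`: sampled area is finite and > 0;
#' * `locality_habitat`: locality codes starting `"l"` are lakes, `"r"`
#'   rivers;
#' * `habitat_enum`, `gear_enum`: habitat in lake/river, gear in
#'   gillnet/seine;
#' * `seine_in_lakes`: seining happens only in lakes;
#' * `catch_unit_ref`, `catch_species_ref`: every catch references an
#'   existing unit and species;
#' * `catch_unique`: at most one record per (unit, species);
#' * `count_nonnegative`: individual counts are >= 0;
#' * `weight_positive_when_caught`: weight must be > 0 whenever
#'   `n_individuals` > 0 (a zero weight would silently delete biomass);
#' * `origin_enum`: registry origins are one of the three valid labels.
#'
#' Downstream computations ([summarize_units()], [aggregate_series()],
#' [run_metrics()]) reject a survey whose report contains errors.
#'
#' @param survey A `survey_table`.
#' @return An object of class `validation_report`: list with `errors` (tibble
#'   `table`, `row`, `rule`, `message`), `warnings`, and counts `n_units`,
#'   `n_species`, `n_records`.
#' @export
validate_survey <- function(survey) {
  stopifnot(inherits(survey, "survey_table"))
  u <- survey$units
  ct <- survey$catches
  reg <- survey$registry
  err <- list()
  fail <- function(table, rows, rule, message) {
    if (length(rows) == 0) return(NULL)
    tibble(table = table, row = as.integer(rows), rule = rule,
           message = message)
  }

  err$unit_dup <- fail("units", which(duplicated(u$unit_id)),
                       "unit_id_unique", "duplicated unit_id")
  err$area <- fail("units", which(!is.finite(u$area_m2) | u$area_m2 <= 0),
                   "area_positive", "area_m2 must be > 0")
  exp_hab <- ifelse(startsWith(u$locality, "l"), "lake",
                    ifelse(startsWith(u$locality, "r"), "river", NA))
  err$loc_hab <- fail("units",
                      which(!is.na(exp_hab) & u$habitat != exp_hab),
                      "locality_habitat",
                      "locality prefix disagrees with habitat")
  err$hab <- fail("units", which(!u$habitat %in% c("lake", "river")),
                  "habitat_enum", "habitat must be lake or river")
  err$gear <- fail("units", which(!u$gear %in% c("gillnet", "seine")),
                   "gear_enum", "gear must be gillnet or seine")
  err$seine <- fail("units",
                    which(u$gear == "seine" & u$habitat != "lake"),
                    "seine_in_lakes", "seining is restricted to lakes")
  err$c_unit <- fail("catches", which(!ct$unit_id %in% u$unit_id),
                     "catch_unit_ref", "catch references unknown unit_id")
  err$c_sp <- fail("catches", which(!ct$species_id %in% reg$species_id),
                   "catch_species_ref",
                   "catch references unknown species_id")
  err$c_dup <- fail("catches",
                    which(duplicated(ct[c("unit_id", "species_id")])),
                    "catch_unique",
                    "more than one record per (unit_id, species_id)")
  err$count <- fail("catches",
                    which(!is.finite(ct$n_individuals) | ct$n_individuals < 0),
                    "count_nonnegative", "n_individuals must be >= 0")
  err$weight <- fail(
    "catches",
    which(is.finite(ct$n_individuals) & ct$n_individuals > 0 &
            (!is.finite(ct$total_weight_g) | ct$total_weight_g <= 0)),
    "weight_positive_when_caught",
    "total_weight_g must be > 0 when n_individuals > 0"
  )
  err$origin <- fail("registry", which(!reg$origin %in% origin_levels),
                     "origin_enum", "origin outside the valid labels")

  errors <- bind_rows(err)
  warnings <- character(0)
  n_uncl <- sum(reg$origin == "unclassified")
  if (n_uncl > 0) {
    warnings <- c(warnings, sprintf(
      "%d unclassified species are excluded from all indices", n_uncl))
  }
  structure(
    list(errors = errors, warnings = warnings,
         n_units = nrow(u), n_species = nrow(reg), n_records = nrow(ct)),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", x$n_units, " units, ", x$n_species,
      " species, ", x$n_records, " catch records\n", sep = "")
  if (nrow(x$errors) == 0) {
    cat("  no errors\n")
  } else {
    cat("  ", nrow(x$errors), " error(s):\n", sep = "")
    print(as.data.frame(x$errors), row.names = FALSE)
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

# Stop with the printed report if the survey has validation errors.
assert_valid <- function(survey) {
  rep <- attr(survey, "validation") %||% validate_survey(survey)
  if (nrow(rep$errors) > 0) {
    print(rep)
    stop("survey has ", nrow(rep$errors),
         " validation error(s); fix them before computing metrics",
         call. = FALSE)
  }
  invisible(survey)
}
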