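test_that("read_registry parses origins and applies the unclassified fallback", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species_id,species_name,origin",
               "a,Alpha alpha,native",
               "b,Beta beta,non_native",
               "c,Gamma gamma,unclassified"), path)
  reg <- read_registry(path)
  expect_equal(nrow(reg), 3)
  expect_equal(as.vector(table(reg$origin)[c("native", "non_native",
                                             "unclassified")]),
               c(1L, 1L, 1L))

  writeLines(c("species_id,species_name,origin",
               "a,Alpha alpha,NA",
               "b,Beta beta,native"), path)
  expect_warning(reg <- read_registry(path), "unclassified")
  expect_equal(reg$origin[reg$species_id == "a"], "unclassified")
})

test_that("read_registry rejects duplicates and empty files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species_id,species_name,origin",
               "a,Alpha,native", "a,Alpha 2,native"), path)
  expect_error(read_registry(path), "duplicate")
  writeLines("species_id,species_name,origin", path)
  expect_error(read_registry(path), "empty")
})

test_that("a registry with the published census structure totals 157 species", {
  reg <- synthetic_species_registry(85, 68, 4)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(reg, path)
  parsed <- read_registry(path)
  expect_equal(nrow(parsed), 157)
  counts <- table(parsed$origin)
  expect_equal(as.vector(counts[c("native", "non_native", "unclassified")]),
               c(85L, 68L, 4L))
})

test_that("read_survey links tables and derives campaign fields", {
  dir <- withr::local_tempdir()
  paths <- write_survey(tiny_survey(), dir)
  survey <- read_survey(paths[["units"]], paths[["catches"]],
                        paths[["registry"]])
  expect_s3_class(survey, "survey_table")
  expect_equal(nrow(survey$units), 3)
  expect_equal(nrow(survey$catches), 5)
  expect_equal(survey$units$season[survey$units$unit_id == "u1"], "Q2")
  expect_equal(survey$units$campaign[survey$units$unit_id == "u3"],
               "2003-Q3")
  expect_equal(nrow(attr(survey, "validation")$errors), 0)
})

test_that("a catch referencing an unknown unit is a named validation error", {
  survey <- tiny_survey()
  survey$catches <- dplyr::bind_rows(
    survey$catches,
    tibble::tibble(unit_id = "X9", species_id = "nat1",
                   n_individuals = 1, total_weight_g = 10))
  rep <- validate_survey(survey)
  bad <- rep$errors[rep$errors$rule == "catch_unit_ref", ]
  expect_equal(nrow(bad), 1)
  expect_equal(bad$row, 6L)
})

test_that("non-positive sampled area is a hard read error", {
  dir <- withr::local_tempdir()
  paths <- write_survey(tiny_survey(), dir)
  units <- readr::read_csv(paths[["units"]], show_col_types = FALSE)
  units$area_m2[1] <- 0
  readr::write_csv(units, paths[["units"]])
  expect_error(read_survey(paths[["units"]], paths[["catches"]],
                           paths[["registry"]]),
               "non-positive")
})

test_that("survey CSVs round-trip byte-identically", {
  for (seed in 1:5) {
    survey <- random_survey(seed, n_units = 17)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    p1 <- write_survey(survey, d1)
    back <- read_survey(p1[["units"]], p1[["catches"]], p1[["registry"]])
    p2 <- write_survey(back, d2)
    for (f in names(p1)) {
      expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                       label = sprintf("%s (seed %d)", f, seed))
    }
  }
})

test_that("validation applies each structural rule exactly once per bad row", {
  survey <- tiny_survey()
  expect_equal(nrow(validate_survey(survey)$errors), 0)

  # seining on a river locality
  bad <- survey
  bad$units$gear[bad$units$unit_id == "u3"] <- "seine"
  rep <- validate_survey(bad)
  expect_equal(rep$errors$rule, "seine_in_lakes")
  expect_equal(nrow(rep$errors), 1)

  # caught individuals without weight
  bad <- survey
  bad$catches$total_weight_g[1] <- 0
  rep <- validate_survey(bad)
  expect_equal(rep$errors$rule, "weight_positive_when_caught")

  # locality prefix vs habitat
  bad <- survey
  bad$units$habitat[bad$units$unit_id == "u3"] <- "lake"
  rep <- validate_survey(bad)
  expect_true("locality_habitat" %in% rep$errors$rule)

  # validation is total: several defects are all reported, once each
  bad <- survey
  bad$units$gear[bad$units$unit_id == "u3"] <- "seine"
  bad$catches$total_weight_g[1] <- 0
  bad$catches <- dplyr::bind_rows(bad$catches, bad$catches[5, ])
  rep <- validate_survey(bad)
  expect_equal(sort(rep$errors$rule),
               sort(c("seine_in_lakes", "weight_positive_when_caught",
                      "catch_unique")))
})

test_that("surveys with validation errors are rejected downstream", {
  bad <- tiny_survey()
  bad$units$area_m2[2] <- -1
  expect_error(suppressMessages(summarize_units(bad)), "validation error")
})
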