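test_that("identical configuration and seed give identical surveys", {
  cfg <- small_config(seed = 42)
  a <- simulate_survey(cfg)
  b <- simulate_survey(cfg)
  expect_identical(a$survey$units, b$survey$units)
  expect_identical(a$survey$catches, b$survey$catches)
  expect_identical(a$truth, b$truth)
  c <- simulate_survey(small_config(seed = 43))
  expect_false(identical(a$survey$catches, c$survey$catches))
})

test_that("the simulator leaves the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_survey(small_config(seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("the null model emits a purely native survey", {
  cfg <- small_config(seed = 3, colonization_rate_per_campaign = 0,
                      initial_nonnative_pool = 0)
  sim <- simulate_survey(cfg)
  us <- contamination_indices(summarize_units(sim$survey))
  expect_true(all(us$R_nn == 0))
  expect_true(all(us$CI_r[!is.na(us$CI_r)] == 0))
  expect_true(all(sim$truth$n_nonnative_resident == 0))
})

test_that("emitted catches are consistent with the registry and pools", {
  cfg <- small_config(seed = 11)
  sim <- simulate_survey(cfg)
  expect_true(all(sim$survey$catches$species_id %in%
                    sim$survey$registry$species_id))
  counts <- table(sim$survey$registry$origin)
  expect_equal(unname(counts[["native"]]), cfg$initial_native_pool)
  expect_equal(unname(counts[["non_native"]]), cfg$initial_nonnative_pool)
  expect_equal(nrow(validate_survey(sim$survey)$errors), 0)
})

test_that("raising the colonization rate never lowers final non-native richness", {
  finals <- function(rate, seed) {
    sim <- simulate_survey(small_config(
      seed = seed, colonization_rate_per_campaign = rate))
    last <- sim$truth[sim$truth$year == max(sim$truth$year), ]
    mean(last$n_nonnative_resident)
  }
  diffs <- vapply(1:30, function(s) finals(0.03, s) - finals(0.005, s),
                  numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("gillnets catch larger-bodied fish than seines", {
  sim <- simulate_survey(default_config(seed = 5))
  per_ind <- sim$survey$catches %>%
    dplyr::inner_join(sim$survey$units[c("unit_id", "gear")],
                      by = "unit_id") %>%
    dplyr::group_by(gear) %>%
    dplyr::summarise(
      mean_mass = mean(total_weight_g / n_individuals))
  expect_gt(per_ind$mean_mass[per_ind$gear == "gillnet"],
            per_ind$mean_mass[per_ind$gear == "seine"])
})

test_that("perfect detection reproduces the true resident fraction exactly", {
  cfg <- small_config(seed = 8, perfect_detection = TRUE)
  sim <- simulate_survey(cfg)
  us <- contamination_indices(summarize_units(sim$survey))
  joined <- dplyr::inner_join(
    us, sim$truth[c("locality", "campaign", "frac_nonnative")],
    by = c("locality", "campaign"))
  ok <- !is.na(joined$CI_r)
  expect_true(any(ok))
  expect_equal(joined$CI_r[ok], joined$frac_nonnative[ok],
               tolerance = 1e-12)
})

test_that("recovery report checks key alignment and summarises bias", {
  sim <- simulate_survey(small_config(seed = 2))
  rep <- recovery_report(sim)
  expect_true(is.finite(rep$bias))
  expect_true(rep$rmse >= abs(rep$bias))
  expect_equal(rep$n, sum(!is.na(
    contamination_indices(summarize_units(sim$survey))$CI_r)))

  truncated <- sim$truth[sim$truth$year > 2000, ]
  expect_error(recovery_report(truncated, sim$survey), "mismatched keys")
})

test_that("invalid configurations are refused before simulation", {
  expect_error(simulate_survey(small_config(flood_multiplier = 0.5)),
               "flood_multiplier")
  expect_error(simulate_survey(small_config(
    colonization_rate_per_campaign = 1.2)), "\\[0, 1\\]")
  expect_error(simulate_survey(small_config(initial_native_pool = 0)),
               "initial_native_pool")
})
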