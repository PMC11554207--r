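test_that("biomass density is weight over area", {
  expect_equal(biomass_density(368, 368), 1)
  expect_equal(biomass_density(0, 247.69), 0)
  expect_equal(biomass_density(100 + 50 + 25, 250), 0.7)
  expect_error(biomass_density(10, 0), "area")
  expect_error(biomass_density(-1, 10), ">= 0")
})

test_that("unit summaries partition richness and biomass by origin", {
  us <- summarize_units(tiny_survey())
  u1 <- us[us$unit_id == "u1", ]
  expect_equal(u1$R_n, 2)
  expect_equal(u1$R_nn, 1)
  expect_equal(u1$B_n, (200 + 100) / 368)   # 0.8152...
  expect_equal(u1$B_nn, 68 / 368)           # 0.1848...
  # the unclassified species contributes to neither class
  expect_equal(u1$B_s, u1$B_n + u1$B_nn)

  u2 <- us[us$unit_id == "u2", ]  # no catches at all
  expect_equal(c(u2$R_n, u2$R_nn, u2$B_n, u2$B_nn), c(0, 0, 0, 0))

  expect_error(summarize_unit(tiny_survey(), "nope"), "unknown unit")
})

test_that("contamination indices reproduce hand-computed values", {
  # year-2000 pool: 26 non-native vs 42 native species, unit biomasses
  s <- tibble::tibble(R_nn = 26, R_n = 42, B_nn = 1, B_n = 1)
  ci <- contamination_indices(s)
  expect_equal(ci$CI_r, 26 / 68, tolerance = 1e-12)
  expect_equal(ci$CI_b, 0.5)
  expect_equal(ci$CI_e, 26 / 68, tolerance = 1e-12)
  expect_equal(ci$CI_a, (0.5 + 26 / 68) / 2, tolerance = 1e-12)
  expect_equal(ci$CI_sq, sqrt(0.5 * 26 / 68), tolerance = 1e-12)
  expect_equal(round(c(ci$CI_r, ci$CI_b, ci$CI_e, ci$CI_a, ci$CI_sq), 5),
               c(0.38235, 0.5, 0.38235, 0.44118, 0.43724))
})

test_that("degenerate assemblages give 0, 0.5, or undefined as appropriate", {
  ci0 <- contamination_indices(
    tibble::tibble(R_nn = 0, R_n = 5, B_nn = 0, B_n = 2))
  expect_equal(c(ci0$CI_r, ci0$CI_b, ci0$CI_e, ci0$CI_a, ci0$CI_sq),
               rep(0, 5))

  ci5 <- contamination_indices(
    tibble::tibble(R_nn = 3, R_n = 3, B_nn = 1.7, B_n = 1.7))
  expect_equal(c(ci5$CI_r, ci5$CI_b, ci5$CI_e, ci5$CI_a, ci5$CI_sq),
               rep(0.5, 5))

  # empty unit: all denominators zero -> undefined, not coerced
  cina <- contamination_indices(
    tibble::tibble(R_nn = 0, R_n = 0, B_nn = 0, B_n = 0))
  expect_true(all(is.na(c(cina$CI_r, cina$CI_b, cina$CI_e, cina$CI_a,
                          cina$CI_sq))))
})

test_that("the multiplicative index defaults to the geometric mean", {
  expect_equal(ci_multiplicative(0.64, 0.55), sqrt(0.64 * 0.55))
  expect_equal(ci_multiplicative(0.64, 0.55, form = "product"),
               0.64 * 0.55)
  s <- tibble::tibble(R_nn = 2, R_n = 3, B_nn = 4, B_n = 1)
  g <- contamination_indices(s)
  p <- contamination_indices(s, ci_sq_form = "product")
  expect_equal(g$CI_sq, sqrt(g$CI_b * g$CI_r))
  expect_equal(p$CI_sq, p$CI_b * p$CI_r)
})

test_that("defined indices stay in [0,1] with CI_sq <= CI_a, and the
           equal-biomass limit collapses CI_b onto CI_r", {
  set.seed(42)
  for (i in 1:200) {
    s <- tibble::tibble(
      R_nn = sample(0:12, 1), R_n = sample(0:12, 1),
      B_nn = round(runif(1, 0, 50), 3), B_n = round(runif(1, 0, 50), 3))
    # keep R = 0 consistent with B = 0 for each origin class
    if (s$R_nn == 0) s$B_nn <- 0
    if (s$R_n == 0) s$B_n <- 0
    ci <- contamination_indices(s)
    vals <- c(ci$CI_r, ci$CI_b, ci$CI_e, ci$CI_a, ci$CI_sq)
    defined <- vals[!is.na(vals)]
    expect_true(all(defined >= 0 & defined <= 1))
    if (!is.na(ci$CI_sq) && !is.na(ci$CI_a)) {
      expect_lte(ci$CI_sq, ci$CI_a + 1e-12)
    }
  }
  # identical per-species biomass: CI_b = CI_r and CI_e amplifies it
  for (i in 1:50) {
    r_nn <- sample(1:12, 1); r_n <- sample(1:12, 1)
    b <- runif(1, 0.1, 10)
    ci <- contamination_indices(tibble::tibble(
      R_nn = r_nn, R_n = r_n, B_nn = r_nn * b, B_n = r_n * b))
    expect_equal(ci$CI_b, ci$CI_r, tolerance = 1e-12)
    expect_gte(abs(ci$CI_e - 0.5), abs(ci$CI_r - 0.5) - 1e-12)
    expect_equal(sign(ci$CI_e - 0.5), sign(ci$CI_r - 0.5))
  }
})

test_that("CI_e increases in non-native biomass and decreases in native", {
  base <- tibble::tibble(R_nn = 3, R_n = 5, B_nn = 2, B_n = 4)
  ci <- function(s) contamination_indices(s)$CI_e
  up <- dplyr::mutate(base, B_nn = B_nn * 1.5)
  down <- dplyr::mutate(base, B_n = B_n * 1.5)
  expect_gt(ci(up), ci(base))
  expect_lt(ci(down), ci(base))
})

test_that("published locality means are internally consistent", {
  ref <- reference_locality_ci()
  expect_equal(nrow(ref), 15)
  idx <- as.matrix(ref[c("CIe", "CIb", "CIa", "CIsq", "CIr")])
  expect_true(all(idx >= 0 & idx <= 1))
  # AM-GM at printed precision: each row's CIsq is at most CIa (+rounding)
  expect_true(all(ref$CIsq <= ref$CIa + 0.005))
})
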