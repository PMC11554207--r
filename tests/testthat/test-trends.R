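test_that("the normality gate detects heavy tails and keeps its nominal size", {
  # heavy-tailed alternative: essentially always rejected
  rejected <- vapply(1:100, function(s) {
    set.seed(s)
    check_normality(rlnorm(200, 0, 1))$p < 0.05
  }, logical(1))
  expect_gte(sum(rejected), 95)

  # normal null: rejection rate near the nominal 5%
  rate <- mean(vapply(1:200, function(s) {
    set.seed(1000 + s)
    check_normality(rnorm(200))$p < 0.05
  }, logical(1)))
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)

  expect_false(check_normality(rep(1, 10))$defined)
  expect_error(check_normality(1:2), "3 <= n")
})

test_that("a constant response yields a null trend", {
  fit <- fit_smooth_trend(seq(0, 17, length.out = 40), rep(3.2, 40))
  expect_gt(fit$p, 0.05)
  expect_equal(fit$edf, 1, tolerance = 0.1)
  expect_equal(fit$beta, 0, tolerance = 1e-10)
})

test_that("a noiseless linear trend with locality offsets is recovered exactly", {
  t <- rep(seq(0, 17, length.out = 30), 3)
  loc <- rep(c("lgar", "lgua", "rbai"), each = 30)
  offsets <- c(lgar = 0, lgua = 1.5, rbai = -2)[loc]
  y <- 2 * t + offsets
  fit <- suppressWarnings(fit_smooth_trend(t, y, locality = loc))
  # the population trend is affine in time
  line <- lm(fit$fitted ~ fit$time)
  expect_lt(max(abs(residuals(line))), 1e-6)
  expect_equal(fit$beta, 2, tolerance = 1e-3)

  # single locality, noiseless: slope to three significant figures
  fit1 <- suppressWarnings(fit_smooth_trend(
    seq(0, 17, length.out = 68), 2 * seq(0, 17, length.out = 68) + 1))
  expect_equal(fit1$beta, 2, tolerance = 0.005)
})

test_that("slope summaries behave under linearity, symmetry and reversal", {
  t <- seq(0, 10, length.out = 25)
  fit <- suppressWarnings(fit_smooth_trend(t, 5 * t + 1))
  sl <- estimate_slope_beta(fit)
  expect_equal(sl[["beta"]], 5, tolerance = 1e-6)
  expect_lt(sl[["sd"]], 1e-6)

  # symmetric rise-then-fall: slope of the fitted trend is about zero
  hump <- suppressWarnings(fit_smooth_trend(t, sin(pi * t / 10)))
  expect_lt(abs(hump$beta), 1e-4)

  # time reversal flips the sign of a noiseless slope
  fwd <- suppressWarnings(fit_smooth_trend(t, 2 * t))
  rev <- suppressWarnings(fit_smooth_trend(max(t) - t, 2 * t))
  expect_equal(rev$beta, -fwd$beta, tolerance = 1e-6)
})

test_that("without AR(1) and penalty the fit reduces to spline regression", {
  set.seed(5)
  t <- seq(0, 17, length.out = 40)
  y <- sin(t / 3) + rnorm(40, 0, 0.2)
  fit <- fit_smooth_trend(t, y, ar1 = FALSE, sp = 0)
  # oracle: OLS on the explicitly constructed cubic regression spline basis
  sm <- mgcv::smoothCon(mgcv::s(t, bs = "cr", k = 10),
                        data = data.frame(t = t), absorb.cons = TRUE)[[1]]
  X <- cbind(1, sm$X)
  ols_fitted <- as.numeric(X %*% qr.coef(qr(X), y))
  expect_lt(max(abs(fit$fitted - ols_fitted)), 1e-8)
})

test_that("the smooth-trend test keeps its size under an iid null", {
  t <- seq_len(40)
  rejected <- vapply(1:200, function(s) {
    set.seed(3000 + s)
    suppressWarnings(fit_smooth_trend(t, rnorm(40)))$p < 0.05
  }, logical(1))
  expect_lte(mean(rejected), 0.10)  # nominal 0.05 plus slack
})

test_that("trend fits validate their inputs", {
  expect_error(fit_smooth_trend(1:5, rnorm(5)), "at least 10")
  expect_error(fit_smooth_trend(1:10, c(rnorm(9), NA)), "non-finite")
  expect_error(fit_smooth_trend(1:10, rnorm(11)), "equal length")
})
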