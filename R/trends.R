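#' Shapiro-Wilk normality gate
#'
#' Wraps the Shapiro-Wilk test used to gate trend modelling: series whose
#' distribution departs from normality (p < 0.05) call for the
#' penalized-smooth route.  The pipeline fits the smooth-trend model
#' unconditionally and reports this gate as metadata, so its behaviour never
#' branches on a data-dependent test.
#'
#' @param series Numeric vector, 3 <= n <= 5000.
#' @return A list: `statistic` (W), `p`, `n`, `defined` (`FALSE` for a
#'   constant series, in which case both are `NA`).
#' @export
check_normality <- function(series) {
  series <- series[is.finite(series)]
  n <- length(series)
  if (n < 3 || n > 5000) stop("need 3 <= n <= 5000 finite values",
                              call. = FALSE)
  if (sd(series) == 0) {
    return(list(statistic = NA_real_, p = NA_real_, n = n, defined = FALSE))
  }
  sw <- shapiro.test(series)
  list(statistic = unname(sw$statistic), p = sw$p.value, n = n,
       defined = TRUE)
}

#' Penalized-spline temporal trend with AR(1) errors
#'
#' Fits the package's standard temporal-trend model to one response series:
#' a penalized cubic regression spline of time (basis dimension `k`), a
#' random intercept per locality (when more than one locality is present),
#' and AR(1) residual correlation between consecutive observations within a
#' locality.  The model is estimated with [mgcv::gamm()] (smooth + nlme
#' engine) by maximum likelihood.
#'
#' Trend significance (`p`) is a likelihood-ratio test of the full model
#' against an intercept-only GLS/LME null with the same AR(1) and
#' random-intercept structure, referred to a chi-square with 2 degrees of
#' freedom (the smooth's fixed linear part plus its wiggliness component).
#' Testing on the variance-component boundary makes this mildly
#' conservative; the smooth's own approximate test is reported alongside as
#' `p_smooth` but is anticonservative under estimated autocorrelation and is
#' not used for decisions.  On degenerate inputs (constant response, or
#' series where the joint fit cannot be estimated) the fitter falls back to
#' a plain penalized spline without correlation structure and says so in
#' `engine`.
#'
#' @param time Numeric vector of observation times in years.
#' @param response Numeric response vector.
#' @param locality Optional factor/character of locality codes for random
#'   intercepts and the AR(1) grouping; a single series is fitted when
#'   omitted.
#' @param transform `"none"` or `"log10p1"` (`log10(x + 1)`, used for
#'   right-skewed seine biomass).
#' @param k Spline basis dimension (default 10).
#' @param ar1 Model AR(1) residual correlation (default `TRUE`).  With
#'   `ar1 = FALSE` the model is an ordinary penalized (or, with `sp = 0`,
#'   unpenalized) spline regression.
#' @param sp Optional fixed smoothing parameter, passed through when
#'   `ar1 = FALSE`.
#' @param label Optional label stored with the fit.
#' @return An object of class `trend_fit`: `n`, `edf`, `ref_df`, `F`, `p`
#'   (likelihood-ratio trend test), `p_smooth`, `adj_r2`, `phi` (AR(1)
#'   coefficient; 0 when not modelled), `beta`/`beta_sd` (OLS slope of the
#'   fitted trend against time, response units per year), `fitted`
#'   (population-level trend at the ordered observation times), `time`,
#'   `response` (transformed, ordered), `locality`, `transform`, `engine`.
#' @export
fit_smooth_trend <- function(time, response, locality = NULL,
                             transform = c("none", "log10p1"), k = 10,
                             ar1 = TRUE, sp = NULL, label = NULL) {
  transform <- match.arg(transform)
  if (length(time) != length(response)) {
    stop("time and response must have equal length", call. = FALSE)
  }
  if (any(!is.finite(response))) stop("non-finite response", call. = FALSE)
  if (length(response) < 10) {
    stop("need at least 10 observations", call. = FALSE)
  }
  y <- if (transform == "log10p1") log10(response + 1) else response
  loc <- factor(if (is.null(locality)) rep("all", length(y)) else locality)
  ord <- order(loc, time)
  df <- data.frame(y = y[ord], t = time[ord], loc = loc[ord])
  multi <- nlevels(droplevels(df$loc)) > 1

  base <- list(label = label, n = nrow(df), k = k, transform = transform,
               time = df$t, response = df$y, locality = df$loc)

  if (sd(df$y) < 1e-12) {
    out <- c(base, list(
      edf = 1, ref_df = 1, F = 0, p = 1, p_smooth = 1, adj_r2 = 0,
      phi = 0, fitted = rep(mean(df$y), nrow(df)), beta = 0, beta_sd = 0,
      engine = "degenerate"))
    class(out) <- "trend_fit"
    return(out)
  }

  fit <- NULL
  engine <- NA_character_
  phi <- 0
  p_trend <- NA_real_

  if (ar1) {
    fit <- tryCatch(fit_gamm_ar1(df, k, multi), error = function(e) NULL)
  }
  if (!is.null(fit)) {
    engine <- "gamm-ar1"
    phi <- fit$phi
    p_trend <- fit$p_lrt
    gam_part <- fit$gam
  } else {
    form <- if (multi) y ~ s(t, bs = "cr", k = k) + s(loc, bs = "re") else
      y ~ s(t, bs = "cr", k = k)
    gam_part <- if (is.null(sp)) {
      mgcv::gam(form, data = df, method = "REML")
    } else {
      mgcv::gam(form, data = df, sp = if (multi) c(sp, NULL) else sp,
                method = "REML")
    }
    engine <- "gam"
    r <- residuals(gam_part, type = "response")
    phi <- lag1_within(r, df$loc)
  }

  st <- summary(gam_part)$s.table
  row <- grep("s\\(t\\)", rownames(st))[1]
  fitted_trend <- as.numeric(
    mgcv::predict.gam(gam_part, newdata = df,
                      exclude = if (multi && engine == "gam") "s(loc)" else NULL)
  )
  if (is.na(p_trend)) p_trend <- st[row, "p-value"]
  slope <- ols_slope(df$t, fitted_trend)
  out <- c(base, list(
    edf = unname(st[row, "edf"]),
    ref_df = unname(st[row, "Ref.df"]),
    F = unname(st[row, "F"]),
    p = unname(p_trend),
    p_smooth = unname(st[row, "p-value"]),
    adj_r2 = summary(gam_part)$r.sq,
    phi = unname(phi),
    fitted = fitted_trend,
    beta = slope[["beta"]], beta_sd = slope[["sd"]],
    engine = engine))
  class(out) <- "trend_fit"
  out
}

# Joint GAMM fit with corAR1 (and locality random intercepts when multi),
# plus the ML likelihood-ratio test against the matching intercept-only null.
fit_gamm_ar1 <- function(df, k, multi) {
  if (multi) {
    f1 <- mgcv::gamm(y ~ s(t, bs = "cr", k = k), data = df,
                     random = list(loc = ~1),
                     correlation = nlme::corAR1(form = ~ 1 | loc),
                     method = "ML")
    f0 <- nlme::lme(y ~ 1, random = ~ 1 | loc, data = df,
                    correlation = nlme::corAR1(form = ~ 1 | loc),
                    method = "ML")
  } else {
    f1 <- mgcv::gamm(y ~ s(t, bs = "cr", k = k), data = df,
                     correlation = nlme::corAR1(form = ~ 1),
                     method = "ML")
    f0 <- nlme::gls(y ~ 1, data = df,
                    correlation = nlme::corAR1(form = ~ 1),
                    method = "ML")
  }
  phi <- unname(coef(f1$lme$modelStruct$corStruct, unconstrained = FALSE))
  lrt <- 2 * (as.numeric(logLik(f1$lme)) - as.numeric(logLik(f0)))
  list(gam = f1$gam, lme = f1$lme, phi = phi,
       p_lrt = pchisq(max(lrt, 0), df = 2, lower.tail = FALSE))
}

# Lag-1 autocorrelation of residuals within groups (consecutive rows only).
lag1_within <- function(r, groups) {
  num <- 0
  den <- sum(r^2)
  for (g in levels(factor(groups))) {
    rg <- r[groups == g]
    if (length(rg) >= 2) {
      num <- num + sum(rg[-1] * rg[-length(rg)])
    }
  }
  if (den > 0) num / den else 0
}

ols_slope <- function(t, y) {
  if (sd(t) == 0) stop("degenerate time span", call. = FALSE)
  f <- lm(y ~ t)
  sm <- summary(f)$coefficients
  c(beta = unname(coef(f)[["t"]]),
    sd = if (nrow(sm) >= 2) unname(sm["t", "Std. Error"]) else 0)
}

#' Linear slope summary of a fitted trend
#'
#' Summarises a fitted smooth trend by the ordinary least-squares slope of
#' its fitted values against time, in response units per year, with the
#' slope's standard error.  For an exactly linear trend this recovers the
#' line's slope with (numerically) zero error; for a symmetric rise-fall
#' trend it is approximately zero.
#'
#' @param fit A `trend_fit` from [fit_smooth_trend()].
#' @return Named numeric vector `c(beta, sd)`.
#' @export
estimate_slope_beta <- function(fit) {
  stopifnot(inherits(fit, "trend_fit"))
  ols_slope(fit$time, fit$fitted)
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit>", if (!is.null(x$label)) x$label else "", "\n")
  cat(sprintf("  n = %d, engine = %s, transform = %s\n", x$n, x$engine,
              x$transform))
  cat(sprintf("  edf = %.2f (ref %.2f), F = %.2f, p = %.3g, adj-R2 = %.3f\n",
              x$edf, x$ref_df, x$F, x$p, x$adj_r2))
  cat(sprintf("  beta = %.4g +/- %.3g per year, phi = %.3f\n",
              x$beta, x$beta_sd, x$phi))
  invisible(x)
}
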