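test_that("KPSS level test separates stationary noise from a random walk", {
  set.seed(101)
  x <- rnorm(200)
  expect_gt(kpss_level_test(x)$p_value, 0.05)
  rw <- cumsum(rnorm(200))
  expect_lt(kpss_level_test(rw)$p_value, 0.05)
  expect_error(kpss_level_test(1:5), "at least 8")
})

test_that("automatic selection keeps iid noise near white noise (exhaustive oracle)", {
  set.seed(240)
  y <- ms(rnorm(240), c(2000, 1))
  fit <- auto_fit(y, max_p = 2, max_q = 2, max_P = 1, max_Q = 1)
  s <- fit$spec
  expect_equal(s$order[2L], 0L)           # d = 0
  expect_equal(s$seasonal_order[2L], 0L)  # D = 0
  total <- s$order[1L] + s$order[3L] + s$seasonal_order[1L] + s$seasonal_order[3L]
  expect_lte(total, 1L)
  # oracle: exhaustive AIC search over the same grid on the same draw
  ex <- auto_fit(y, max_p = 2, max_q = 2, max_P = 1, max_Q = 1, stepwise = FALSE)
  expect_equal(fit$spec$aic, ex$spec$aic, tolerance = 1e-6)
})

test_that("a seasonal signal is fitted well enough to beat the raw variance", {
  set.seed(12)
  m <- rep(1:12, length.out = 180)
  y <- ms(10 + 4 * sin(2 * pi * m / 12) + rnorm(180, 0, 0.5), c(2000, 1))
  fit <- auto_fit(y)
  rmse <- sqrt(mean(sarima_residuals(fit)^2))
  expect_lt(rmse, sd(y$values))
})

test_that("constant series yield a flagged degenerate fit with constant forecast", {
  y <- ms(rep(7, 60), c(2000, 1), "SM", "kg/m3")
  fit <- auto_fit(y)
  expect_true(fit$degenerate)
  expect_equal(fit$spec$sigma2, 0)
  fc <- forecast_sarima(fit, 6)
  expect_equal(fc$point$values, rep(7, 6))
  expect_equal(fc$lower$values, fc$upper$values)
})

test_that("mean model and random walk forecasts match their closed forms", {
  set.seed(33)
  y <- ms(rnorm(120, mean = 5), c(2000, 1))
  f0 <- forecast_sarima(fit_sarima(y, c(0, 0, 0)), 8)
  expect_equal(f0$point$values, rep(mean(y$values), 8), tolerance = 1e-6)
  # forecasts of a fitted model are deterministic
  f0b <- forecast_sarima(fit_sarima(y, c(0, 0, 0)), 8)
  expect_identical(f0$point$values, f0b$point$values)

  rw <- fit_sarima(y, c(0, 1, 0))
  fr <- forecast_sarima(rw, 10)
  expect_equal(fr$point$values, rep(y$values[120], 10), tolerance = 1e-8)
  half <- (fr$upper$values - fr$lower$values) / 2
  expect_equal(half / half[1L], sqrt(1:10), tolerance = 1e-6)
  # forecast index continues the training index
  expect_equal(fr$point$start, c(2010L, 1L))
})

test_that("intervals nest across levels and never shrink for integrated fits", {
  set.seed(44)
  y <- ms(cumsum(rnorm(100)), c(2000, 1))
  fit <- fit_sarima(y, c(0, 1, 0))
  f95 <- forecast_sarima(fit, 12, level = 0.95)
  f99 <- forecast_sarima(fit, 12, level = 0.99)
  expect_true(all(f99$lower$values <= f95$lower$values))
  expect_true(all(f99$upper$values >= f95$upper$values))
  expect_true(all(f95$lower$values <= f95$point$values))
  expect_true(all(f95$point$values <= f95$upper$values))
  expect_true(all(diff(f95$upper$values - f95$lower$values) > -1e-10))
  expect_error(forecast_sarima(fit, 12, level = 1.2), "level")
  expect_error(forecast_sarima(fit, 0), "horizon")
})

test_that("Ljung-Box detects autocorrelation and respects its preconditions", {
  set.seed(55)
  ar1 <- as.numeric(stats::filter(rnorm(200), 0.8, method = "recursive"))
  expect_lt(ljung_box(ar1, lags = 12)$p_value, 0.01)
  iid <- rnorm(200)
  lb <- ljung_box(iid, lags = 12, fitted_df = 2)
  expect_gt(lb$statistic, 0)
  expect_error(ljung_box(rnorm(10), lags = 12), "smaller than the series")
  expect_error(ljung_box(rnorm(50), lags = 5, fitted_df = 5), "smaller than lags")
})

test_that("published-coefficient forecasting matches the estimation engine", {
  # dual route: hand-rolled polynomial recursion vs stats::arima with the
  # same coefficients held fixed
  set.seed(66)
  m <- rep(1:12, length.out = 144)
  y <- ms(15 + 2.5 * sin(2 * pi * m / 12) + as.numeric(
    stats::filter(rnorm(144, 0, 0.8), 0.3, method = "recursive")), c(2000, 1))
  spec <- published_sm_models()[["10"]]   # (0,0,1)(0,1,1)[12]
  ours <- apply_published_model(spec, y, 12)
  ref <- stats::arima(as_ts(y), order = c(0, 0, 1),
                      seasonal = list(order = c(0, 1, 1), period = 12),
                      fixed = c(spec$ma, spec$sma), include.mean = FALSE,
                      transform.pars = FALSE)
  pr <- stats::predict(ref, n.ahead = 12)
  expect_equal(ours$point$values, as.numeric(pr$pred), tolerance = 0.02)
  # psi-weight widening profile agrees with the state-space standard errors
  half <- (ours$upper$values - ours$lower$values) / 2
  se_ref <- as.numeric(pr$se)
  expect_equal(half / half[1L], se_ref / se_ref[1L], tolerance = 0.05)
})

test_that("an all-zero-coefficient integrated spec is a random walk", {
  y <- ms(c(3, 5, 4, 6, 8, 7, 9, 11, 10, 12), c(2020, 1))
  spec <- sarima_spec(c(0, 1, 0))
  fc <- apply_published_model(spec, y, 5)
  expect_equal(fc$point$values, rep(12, 5))
  expect_error(apply_published_model(spec, ms(1, c(2020, 1)), 3),
               "insufficient history")
})

test_that("lag-polynomial filtering round-trips exactly", {
  # difference/convolve with the full AR polynomial, then invert recursively
  set.seed(77)
  y <- rnorm(80)
  spec <- sarima_spec(c(2, 1, 0), c(1, 1, 0), 12,
                      ar = c(0.4, -0.2), sar = 0.3)
  po <- soilwb:::.sarima_polys(spec)
  a <- po$ar
  n <- length(y)
  pa <- length(a) - 1L
  w <- vapply((pa + 1):n, function(t) sum(a * y[t - 0:pa]), numeric(1))
  # invert: y_t = w_t - sum_{i>=1} a_i y_{t-i}, seeded with the first pa values
  y2 <- c(y[1:pa], numeric(n - pa))
  for (t in (pa + 1):n) y2[t] <- w[t - pa] - sum(a[-1] * y2[t - 1:pa])
  expect_equal(y2, y, tolerance = 1e-10)
  # the MA side of the published 10 cm model expands to the printed cross terms
  po10 <- soilwb:::.sarima_polys(published_sm_models()[["10"]])
  expect_equal(po10$ma[c(1, 2, 13, 14)],
               c(1, -0.5852, -0.7593, 0.5852 * 0.7593), tolerance = 1e-10)
})

test_that("model reports carry orders, criteria and residual diagnostics", {
  set.seed(88)
  y <- ms(rnorm(150, 20, 2), c(2000, 1), "SM10", "kg/m3")
  fit <- auto_fit(y, max_p = 2, max_q = 2, max_P = 1, max_Q = 1)
  rep_ <- sarima_report(fit)
  expect_true(all(c("p", "d", "q", "P", "D", "Q", "aic", "bic", "ljung_box_p")
                  %in% names(rep_)))
  expect_gte(rep_$ljung_box_p, 0)
  expect_false(rep_$degenerate)
})
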