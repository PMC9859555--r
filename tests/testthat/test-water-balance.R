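test_that("the monthly increment matches the printed worked examples", {
  cfg <- wb_config()
  # dry month: increment is minus the evaporation, regardless of the scale
  expect_equal(delta_beta(0, 10.8614, 0, cfg), -10.8614)
  expect_equal(delta_beta(0, 10.8614, 0, wb_config(1)), -10.8614)
  expect_lt(abs(delta_beta(88.0504, 4.5560, 0.0170, cfg) - (-1.6379)),
            printed_tol)
  expect_equal(delta_beta(0, 0, 0, cfg), 0)
  expect_error(delta_beta(-1, 0, 0, cfg), ">= 0")
  expect_error(wb_config(0), "> 0")
})

test_that("increment is linear in (p, se, ic) and in the precipitation scale", {
  set.seed(8)
  p <- runif(20, 0, 300); se <- runif(20, 0, 40); ic <- runif(20, 0, 0.5)
  d1 <- delta_beta(p, se, ic, wb_config(1 / 30))
  d2 <- delta_beta(p, se, ic, wb_config(2 / 30))
  expect_equal(d2 - d1, p / 30, tolerance = 1e-12)
  expect_equal(delta_beta(2 * p, 2 * se, 2 * ic, wb_config(1 / 30)), 2 * d1,
               tolerance = 1e-12)
})

test_that("the increment series reproduces the printed forecast-window column", {
  fx <- xilingol_forecast_drivers()
  ds <- xilingol_forecast_driver_set()
  im <- intercept_max(max(ds$lai$values))
  db <- delta_beta_series(ds, interception_params(im, 1), wb_config(1 / 30))
  expect_lt(max(abs(db$values - fx$dbeta_ref)), printed_tol)
  # zero-precipitation record collapses to -SE
  dry <- driver_set(
    monthly_series(rep(0, 21), ds$p$start, "P", "mm/month"),
    ds$se, ds$ndvi, ds$lai, ds$vcr)
  db0 <- delta_beta_series(dry, interception_params(im, 1), wb_config(1 / 30))
  expect_equal(db0$values, -fx$SE)
})

test_that("noise-free depth-coefficient recovery is exact", {
  set.seed(40)
  db <- ms(rnorm(60, -8, 10), name = "dbeta")
  gamma <- -0.1357
  beta <- Reduce(function(b, d) b + gamma * d, db$values[-60], init = 50,
                 accumulate = TRUE)
  sm <- ms(beta, name = "SM40", unit = "kg/m3")
  fit <- fit_depth_model(sm, db, depth_cm = 40)
  expect_equal(fit$gamma, gamma, tolerance = 1e-10)
  expect_equal(fit$alpha, 1)
  # a constant moisture series has no response to the increment
  cst <- ms(rep(42, 60), name = "SM40", unit = "kg/m3")
  expect_equal(fit_depth_model(cst, db)$gamma, 0, tolerance = 1e-12)
})

test_that("joint (alpha, gamma) estimation matches the two-regressor OLS oracle", {
  set.seed(96)
  n <- 96
  db <- ms(rnorm(n, 0, 10), name = "dbeta")
  beta <- numeric(n)
  beta[1] <- 50
  for (t in 2:n) beta[t] <- 0.95 * beta[t - 1] - 0.07 * db$values[t - 1] +
      rnorm(1, 0, 0.1)
  # the AR(0.95) state relaxes toward 0 and fluctuates on both sides of it,
  # so keep the default (sign-free) unit tag
  sm <- ms(beta, name = "SM")
  fit <- fit_depth_model(sm, db, depth_cm = 40, estimate_alpha = TRUE)
  # closed-form two-regressor least squares on the same draws
  X <- cbind(beta[-n], db$values[-n])
  y <- beta[-1]
  co <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(fit$alpha), co[1], tolerance = 1e-10)
  expect_equal(unname(fit$gamma), co[2], tolerance = 1e-10)
  r <- y - X %*% co
  se <- sqrt(drop(crossprod(r)) / (n - 3) * diag(solve(crossprod(X))))
  expect_lt(abs(fit$alpha - 0.95), 3 * se[1])
  expect_lt(abs(fit$gamma - (-0.07)), 3 * se[2])
})

test_that("depth fitting rejects degenerate inputs", {
  db_const <- ms(rep(-5, 30), name = "dbeta")
  sm <- ms(50 + rnorm(30), name = "SM", unit = "kg/m3")
  expect_error(fit_depth_model(sm, db_const), "constant")
  expect_error(fit_depth_model(ms(1:3, name = "a", unit = "kg/m3"),
                               ms(c(1, 5, 2), name = "d")), "at least 4")
})

test_that("the recursion iterates, floors at zero and honors (alpha, gamma)", {
  db <- ms(c(10, -10), c(2022, 4), "dbeta")
  # identity dynamics
  m0 <- depth_model(40, gamma = 0, alpha = 1)
  expect_equal(forecast_recursive(50, db, m0)$values, c(50, 50))
  # hand iteration
  expect_equal(forecast_recursive(50, db, depth_model(40, -0.1))$values,
               c(49, 50))
  # geometric decay
  db3 <- ms(rep(0, 3), c(2022, 4), "dbeta")
  expect_equal(forecast_recursive(100, db3, depth_model(40, 0, alpha = 0.5))$values,
               c(50, 25, 12.5))
  # flooring: a huge negative increment cannot push moisture below zero
  big <- ms(c(1000, 0), c(2022, 4), "dbeta")
  out <- forecast_recursive(5, big, depth_model(40, -1))
  expect_equal(out$values, c(0, 0))
  expect_error(forecast_recursive(-1, db, m0), ">= 0")
  expect_equal(forecast_recursive(50, db, m0)$start, c(2022L, 4L))
})

test_that("noisy recovery bias shrinks as the record grows", {
  gamma <- -0.1357
  bias <- vapply(c(48, 96, 192), function(n) {
    est <- vapply(1:60, function(s) {
      set.seed(7000 + 13 * n + s)
      db <- rnorm(n, -8, 10)
      beta <- numeric(n); beta[1] <- 50
      for (t in 2:n) beta[t] <- beta[t - 1] + gamma * db[t - 1] + rnorm(1, 0, 0.6)
      fit_depth_model(ms(beta, name = "SM", unit = "kg/m3"),
                      ms(db, name = "dbeta"))$gamma
    }, numeric(1))
    abs(mean(est) - gamma)
  }, numeric(1))
  expect_lt(bias[3], 0.01)
  expect_lt(bias[3], bias[1] + 0.005)
})
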