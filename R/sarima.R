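#' Seasonal ARIMA model specification
#'
#' Plain-value description of a (possibly fitted) seasonal ARIMA model:
#' nonseasonal order `(p, d, q)`, seasonal order `(P, D, Q)` at a fixed
#' period, and coefficient vectors in the R sign convention
#' (`phi(B) = 1 - ar1 B - ...`, `theta(B) = 1 + ma1 B + ...`, seasonal
#' polynomials likewise at lag `period`). Used both to report fitted models
#' and to feed fixed published coefficients to [apply_published_model()].
#'
#' @param order integer `(p, d, q)`.
#' @param seasonal_order integer `(P, D, Q)`.
#' @param period seasonal period (12 for monthly data); must be `>= 2`
#'   whenever any seasonal order is nonzero.
#' @param ar,ma,sar,sma coefficient vectors with lengths `p`, `q`, `P`, `Q`.
#' @param sigma2 innovation variance, `>= 0` (NA if unknown).
#' @param aic,bic information criteria of the fit (NA if unknown).
#' @return an object of class `sarima_spec`.
#' @export
sarima_spec <- function(order, seasonal_order = c(0L, 0L, 0L), period = 12L,
                        ar = numeric(), ma = numeric(),
                        sar = numeric(), sma = numeric(),
                        sigma2 = NA_real_, aic = NA_real_, bic = NA_real_) {
  order <- as.integer(order); seasonal_order <- as.integer(seasonal_order)
  if (length(order) != 3L || any(order < 0L)) stop("order must be 3 nonnegative integers", call. = FALSE)
  if (length(seasonal_order) != 3L || any(seasonal_order < 0L)) {
    stop("seasonal_order must be 3 nonnegative integers", call. = FALSE)
  }
  if (any(seasonal_order > 0L) && period < 2L) {
    stop("period must be >= 2 for a seasonal model", call. = FALSE)
  }
  if (length(ar) != order[1L] || length(ma) != order[3L] ||
      length(sar) != seasonal_order[1L] || length(sma) != seasonal_order[3L]) {
    stop("coefficient vector lengths must equal their orders", call. = FALSE)
  }
  if (!is.na(sigma2) && sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  structure(list(order = order, seasonal_order = seasonal_order,
                 period = as.integer(period),
                 ar = as.numeric(ar), ma = as.numeric(ma),
                 sar = as.numeric(sar), sma = as.numeric(sma),
                 sigma2 = sigma2, aic = aic, bic = bic),
            class = "sarima_spec")
}

#' @export
print.sarima_spec <- function(x, ...) {
  cat(sprintf("<sarima_spec> (%d,%d,%d)(%d,%d,%d)[%d]  AIC=%s BIC=%s\n",
              x$order[1L], x$order[2L], x$order[3L],
              x$seasonal_order[1L], x$seasonal_order[2L], x$seasonal_order[3L],
              x$period,
              if (is.na(x$aic)) "NA" else sprintf("%.2f", x$aic),
              if (is.na(x$bic)) "NA" else sprintf("%.2f", x$bic)))
  invisible(x)
}

# ---- stationarity / differencing-order selection -------------------------

#' KPSS level-stationarity test
#'
#' Tests the null of level stationarity. The statistic is the scaled sum of
#' squared partial sums of demeaned values over a Bartlett-window long-run
#' variance with `trunc(4 (n/100)^{1/4})` lags; the p-value is interpolated
#' from the standard critical-value table (0.347, 0.463, 0.574, 0.739 for
#' 10%, 5%, 2.5%, 1%) and clamped to [0.01, 0.10].
#'
#' @param x numeric series.
#' @return list with `statistic` and `p_value`.
#' @export
kpss_level_test <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("KPSS test needs at least 8 observations", call. = FALSE)
  e <- x - mean(x)
  s <- cumsum(e)
  l <- trunc(4 * (n / 100)^0.25)
  lrv <- sum(e^2) / n
  if (l > 0L) {
    for (k in seq_len(l)) {
      w <- 1 - k / (l + 1)
      lrv <- lrv + 2 * w * sum(e[(k + 1):n] * e[1:(n - k)]) / n
    }
  }
  stat <- if (lrv <= 0) Inf else sum(s^2) / (n^2 * lrv)
  cv <- c(0.347, 0.463, 0.574, 0.739)
  pv <- c(0.10, 0.05, 0.025, 0.01)
  p <- stats::approx(cv, pv, xout = stat, rule = 2L)$y
  list(statistic = stat, p_value = p)
}

# number of ordinary differences needed for level stationarity (KPSS at 0.05)
.select_d <- function(x, alpha = 0.05, max_d = 2L) {
  d <- 0L
  while (d < max_d && length(x) >= 8L && stats::sd(x) > 0 &&
         kpss_level_test(x)$p_value < alpha) {
    x <- diff(x)
    d <- d + 1L
  }
  d
}

# one seasonal difference when the STL seasonal strength exceeds 0.64
.select_D <- function(x, period, threshold = 0.64) {
  if (period < 2L || length(x) < 2L * period + 4L || stats::sd(x) == 0) return(0L)
  fit <- stats::stl(stats::ts(x, frequency = period), s.window = "periodic")
  rem <- fit$time.series[, "remainder"]
  sea <- fit$time.series[, "seasonal"]
  fs <- max(0, 1 - stats::var(rem) / stats::var(rem + sea))
  if (fs >= threshold) 1L else 0L
}

# ---- fitting --------------------------------------------------------------

.spec_from_arima <- function(fit, order, seasonal, period) {
  co <- stats::coef(fit)
  pick <- function(prefix, k) {
    if (k == 0L) return(numeric())
    unname(co[paste0(prefix, seq_len(k))])
  }
  sarima_spec(order, seasonal, period,
              ar = pick("ar", order[1L]), ma = pick("ma", order[3L]),
              sar = pick("sar", seasonal[1L]), sma = pick("sma", seasonal[3L]),
              sigma2 = fit$sigma2,
              aic = fit$aic, bic = stats::BIC(fit))
}

#' Fit a seasonal ARIMA model of fixed order
#'
#' Thin wrapper around [stats::arima()] (maximum likelihood with a
#' state-space innovations representation, CSS-initialised) that returns a
#' `sarima_fit` carrying the fitted object, its [sarima_spec()] summary and
#' the training series. A mean term is included only when `d + D = 0`.
#'
#' @param series a `monthly_series`.
#' @param order `(p, d, q)`.
#' @param seasonal_order `(P, D, Q)`.
#' @param period seasonal period (default 12).
#' @param method estimation method passed to [stats::arima()].
#' @return an object of class `sarima_fit`.
#' @export
fit_sarima <- function(series, order, seasonal_order = c(0L, 0L, 0L),
                       period = 12L, method = "CSS-ML") {
  fit <- stats::arima(as_ts(series), order = order,
                      seasonal = list(order = seasonal_order, period = period),
                      include.mean = (order[2L] + seasonal_order[2L] == 0L),
                      method = method)
  structure(list(fit = fit,
                 spec = .spec_from_arima(fit, order, seasonal_order, period),
                 series = series, degenerate = FALSE, log = character()),
            class = "sarima_fit")
}

.degenerate_fit <- function(series, period) {
  structure(list(fit = NULL,
                 spec = sarima_spec(c(0L, 0L, 0L), c(0L, 0L, 0L), period,
                                    sigma2 = 0),
                 series = series, degenerate = TRUE,
                 constant = series$values[1L], log = "constant series"),
            class = "sarima_fit")
}

#' @export
print.sarima_fit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<sarima_fit> degenerate (constant series at %.4g)\n", x$constant))
  } else {
    cat("<sarima_fit> "); print(x$spec)
  }
  invisible(x)
}

# try one candidate; NULL if it does not converge
.try_candidate <- function(y, order, seasonal, period) {
  for (m in c("CSS-ML", "ML")) {
    fit <- tryCatch(
      suppressWarnings(stats::arima(
        y, order = order,
        seasonal = list(order = seasonal, period = period),
        include.mean = (order[2L] + seasonal[2L] == 0L), method = m)),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$aic)) return(fit)
  }
  NULL
}

#' Automatic seasonal ARIMA order selection
#'
#' Reproduces the usual automatic-selection recipe: one seasonal difference
#' is taken when the STL seasonal strength exceeds 0.64, the ordinary
#' differencing order `d` (at most 2) is then chosen by repeated KPSS
#' level-stationarity testing at the 5% level, and the ARMA orders are found
#' by a stepwise AIC search over `p, q <= max_p, max_q` and seasonal
#' `P, Q <= max_P, max_Q`. The search starts from the four standard seeds
#' ((2,2)(1,1), (0,0)(0,0), (1,0)(1,0), (0,1)(0,1)) and repeatedly moves one
#' order up or down while the AIC improves; ties are broken by BIC, then by
#' total order. `stepwise = FALSE` searches the full grid instead (used to
#' verify the stepwise search on small grids). Candidates that fail to
#' converge are skipped and recorded in the result's `log`; a constant
#' series yields a degenerate white-noise fit with `sigma2 = 0`.
#'
#' Series shorter than `2 * period + 4` are searched without seasonal terms.
#'
#' @param series a `monthly_series`.
#' @param max_p,max_q,max_P,max_Q search limits (defaults 5, 5, 2, 2).
#' @param period seasonal period (default 12).
#' @param stepwise use the stepwise search (default) or the full grid.
#' @return a `sarima_fit` (see [fit_sarima()]); `$log` lists skipped
#'   candidates.
#' @export
auto_fit <- function(series, max_p = 5L, max_q = 5L, max_P = 2L, max_Q = 2L,
                     period = 12L, stepwise = TRUE) {
  y <- as_ts(series)
  n <- length(y)
  if (stats::sd(series$values) == 0) return(.degenerate_fit(series, period))

  seasonal_search <- n >= 2L * period + 4L
  D <- if (seasonal_search) .select_D(series$values, period) else 0L
  yd <- if (D > 0L) diff(series$values, lag = period, differences = D) else series$values
  d <- .select_d(yd)
  if (!seasonal_search) max_P <- max_Q <- 0L

  skipped <- character()
  cache <- new.env(parent = emptyenv())
  evaluate <- function(p, q, P, Q) {
    key <- paste(p, q, P, Q, sep = ".")
    if (!is.null(cache[[key]])) return(cache[[key]])
    npar <- p + q + P + Q + 1L
    res <- if (npar >= n / 2) NULL else
      .try_candidate(y, c(p, d, q), c(P, D, Q), period)
    if (is.null(res)) {
      skipped <<- c(skipped, key)
      res <- list(aic = Inf)
    }
    cache[[key]] <- res
    res
  }
  score <- function(fit, p, q, P, Q) {
    if (!is.finite(fit$aic)) return(c(Inf, Inf, Inf))
    c(fit$aic, stats::BIC(fit), p + q + P + Q)
  }
  better <- function(a, b) {  # lexicographic AIC, BIC, total order
    if (!is.finite(a[1L])) return(FALSE)   # failed candidate never wins
    if (!is.finite(b[1L])) return(TRUE)
    d1 <- a[1L] - b[1L]
    if (abs(d1) > 1e-6) return(d1 < 0)
    d2 <- a[2L] - b[2L]
    if (abs(d2) > 1e-6) return(d2 < 0)
    a[3L] < b[3L]
  }

  grid <- if (stepwise) {
    seeds <- rbind(c(2L, 2L, min(1L, max_P), min(1L, max_Q)),
                   c(0L, 0L, 0L, 0L),
                   c(1L, 0L, min(1L, max_P), 0L),
                   c(0L, 1L, 0L, min(1L, max_Q)))
    seeds[, 1L] <- pmin(seeds[, 1L], max_p)
    seeds[, 2L] <- pmin(seeds[, 2L], max_q)
    unique(seeds)
  } else {
    as.matrix(expand.grid(p = 0:max_p, q = 0:max_q, P = 0:max_P, Q = 0:max_Q))
  }

  best <- NULL; best_score <- c(Inf, Inf, Inf); best_ord <- c(0L, 0L, 0L, 0L)
  consider <- function(p, q, P, Q) {
    fit <- evaluate(p, q, P, Q)
    sc <- score(fit, p, q, P, Q)
    if (better(sc, best_score)) {
      best <<- fit; best_score <<- sc; best_ord <<- c(p, q, P, Q)
      TRUE
    } else FALSE
  }
  for (i in seq_len(nrow(grid))) do.call(consider, as.list(grid[i, ]))

  if (stepwise) {
    repeat {
      o <- best_ord
      moved <- FALSE
      for (j in 1:4) {
        lim <- c(max_p, max_q, max_P, max_Q)[j]
        for (step in c(-1L, 1L)) {
          cand <- o
          cand[j] <- cand[j] + step
          if (cand[j] < 0L || cand[j] > lim) next
          if (do.call(consider, as.list(cand))) moved <- TRUE
        }
      }
      if (!moved) break
    }
  }

  if (is.null(best) || !is.finite(best$aic)) {
    stop("no seasonal ARIMA candidate converged", call. = FALSE)
  }
  order <- c(best_ord[1L], d, best_ord[2L])
  seasonal <- c(best_ord[3L], D, best_ord[4L])
  structure(list(fit = best,
                 spec = .spec_from_arima(best, order, seasonal, period),
                 series = series, degenerate = FALSE, log = skipped),
            class = "sarima_fit")
}

# ---- forecasting ----------------------------------------------------------

.forecast_result <- function(point, se, start, name, level) {
  z <- stats::qnorm((1 + level) / 2)
  structure(list(
    point = monthly_series(point, start, name, "dimensionless"),
    lower = monthly_series(point - z * se, start, name, "dimensionless"),
    upper = monthly_series(point + z * se, start, name, "dimensionless"),
    level = level), class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast_result> h = %d, level = %.2f\n",
              length(x$point$values), x$level))
  invisible(x)
}

#' Forecast from a fitted seasonal ARIMA model
#'
#' Point forecasts and Gaussian prediction intervals from the innovations
#' representation ([stats::predict] on the underlying fit). The forecast
#' month index continues directly after the training series. Degenerate
#' (constant-series) fits forecast the constant with zero-width intervals.
#'
#' @param fitted a `sarima_fit` from [auto_fit()] or [fit_sarima()].
#' @param horizon number of months ahead, `>= 1`.
#' @param level central interval coverage in (0, 1), default 0.95.
#' @return a `forecast_result` with `point`, `lower`, `upper`
#'   (`monthly_series`) and `level`.
#' @export
forecast_sarima <- function(fitted, horizon, level = 0.95) {
  stopifnot(inherits(fitted, "sarima_fit"))
  if (!is.numeric(horizon) || horizon < 1L) stop("horizon must be >= 1", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  horizon <- as.integer(horizon)
  e <- series_end(fitted$series)
  start <- .index_ym(.ym_index(e[1L], e[2L]) + 1L)
  if (fitted$degenerate) {
    return(.forecast_result(rep(fitted$constant, horizon), rep(0, horizon),
                            start, fitted$series$name, level))
  }
  pr <- stats::predict(fitted$fit, n.ahead = horizon)
  .forecast_result(as.numeric(pr$pred), as.numeric(pr$se), start,
                   fitted$series$name, level)
}

#' Residual white-noise (Ljung-Box) test
#'
#' Portmanteau test that the first `lags` residual autocorrelations are
#' jointly zero, with the chi-square degrees of freedom reduced by the
#' number of ARMA coefficients estimated in the model that produced the
#' residuals.
#'
#' @param residuals numeric residual series.
#' @param lags number of autocorrelations tested (default 12, one season).
#' @param fitted_df number of estimated ARMA coefficients (default 0); must
#'   be smaller than `lags`.
#' @return list with `statistic` and `p_value`.
#' @export
ljung_box <- function(residuals, lags = 12L, fitted_df = 0L) {
  n <- length(residuals)
  if (lags >= n) stop("lags must be smaller than the series length", call. = FALSE)
  if (fitted_df >= lags) stop("fitted_df must be smaller than lags", call. = FALSE)
  bt <- stats::Box.test(residuals, lag = lags, type = "Ljung-Box", fitdf = fitted_df)
  list(statistic = unname(bt$statistic), p_value = unname(bt$p.value))
}

#' Residuals of a seasonal ARIMA fit
#' @param fitted a `sarima_fit`.
#' @return numeric residual vector.
#' @export
sarima_residuals <- function(fitted) {
  if (fitted$degenerate) return(rep(0, length(fitted$series$values)))
  as.numeric(stats::residuals(fitted$fit))
}

#' Number of estimated ARMA coefficients of a fit
#' @param fitted a `sarima_fit`.
#' @return integer count (excludes the mean term).
#' @export
sarima_df <- function(fitted) {
  s <- fitted$spec
  s$order[1L] + s$order[3L] + s$seasonal_order[1L] + s$seasonal_order[3L]
}

# ---- fixed published coefficients -----------------------------------------

# convolution product of polynomial coefficient vectors (constant term first)
.polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

# expand a seasonal polynomial to the base lag grid
.seasonal_poly <- function(coefs, period) {
  out <- numeric(length(coefs) * period + 1L)
  out[1L] <- 1
  for (j in seq_along(coefs)) out[j * period + 1L] <- coefs[j]
  out
}

# full AR-side and MA-side lag polynomials of a sarima_spec
.sarima_polys <- function(spec) {
  a <- c(1, if (spec$order[1L]) -spec$ar else NULL)
  a <- .polymul(a, .seasonal_poly(if (spec$seasonal_order[1L]) -spec$sar else numeric(),
                                  spec$period))
  for (i in seq_len(spec$order[2L])) a <- .polymul(a, c(1, -1))
  for (i in seq_len(spec$seasonal_order[2L])) {
    a <- .polymul(a, c(1, rep(0, spec$period - 1L), -1))
  }
  m <- c(1, if (spec$order[3L]) spec$ma else NULL)
  m <- .polymul(m, .seasonal_poly(if (spec$seasonal_order[3L]) spec$sma else numeric(),
                                  spec$period))
  list(ar = a, ma = m)
}

#' Forecast a history with fixed published SARIMA coefficients
#'
#' Applies a fully specified seasonal ARIMA model to a user series without
#' any re-estimation, so published model equations can be run on new
#' history. This is an independent implementation of the SARIMA predictor:
#' the AR/MA/differencing factors are expanded into full lag polynomials,
#' residuals are recovered by the conditional innovation recursion (zero
#' initialisation over the pre-sample), point forecasts follow the ARMA
#' recursion with future innovations set to zero, and interval widths come
#' from the psi-weight expansion. The innovation variance is taken from
#' `spec$sigma2` when present and otherwise estimated from the filtered
#' residuals.
#'
#' @param spec a [sarima_spec()] with fixed coefficients.
#' @param history a `monthly_series` at least as long as the full AR
#'   polynomial (differencing included).
#' @param horizon months ahead, `>= 1`.
#' @param level central interval coverage, default 0.95.
#' @return a `forecast_result`.
#' @export
apply_published_model <- function(spec, history, horizon, level = 0.95) {
  stopifnot(inherits(spec, "sarima_spec"))
  if (!is.numeric(horizon) || horizon < 1L) stop("horizon must be >= 1", call. = FALSE)
  horizon <- as.integer(horizon)
  y <- history$values
  n <- length(y)
  po <- .sarima_polys(spec)
  pa <- length(po$ar) - 1L   # AR-side memory, differencing included
  qm <- length(po$ma) - 1L
  if (n <= pa) {
    stop("insufficient history: need more than ", pa, " observations", call. = FALSE)
  }
  a <- if (pa) po$ar[-1L] else numeric()
  m <- if (qm) po$ma[-1L] else numeric()

  # conditional residual recursion over the sample
  eps <- numeric(n)
  for (t in (pa + 1L):n) {
    val <- y[t] + if (pa) sum(a * y[t - seq_len(pa)]) else 0
    if (qm) {
      j <- seq_len(min(qm, t - 1L))
      val <- val - sum(m[j] * eps[t - j])
    }
    eps[t] <- val
  }
  sigma2 <- if (!is.na(spec$sigma2) && spec$sigma2 > 0) spec$sigma2 else
    mean(eps[(pa + 1L):n]^2)

  # point forecasts: future innovations zero, known ones kept
  yy <- c(y, numeric(horizon))
  ee <- c(eps, numeric(horizon))
  for (h in seq_len(horizon)) {
    t <- n + h
    val <- -(if (pa) sum(a * yy[t - seq_len(pa)]) else 0)
    if (qm) {
      j <- seq_len(qm)
      keep <- (t - j) <= n & (t - j) >= 1L
      if (any(keep)) val <- val + sum(m[j[keep]] * ee[t - j[keep]])
    }
    yy[t] <- val
  }

  # psi weights by polynomial division ma/ar
  psi <- numeric(horizon)
  psi0 <- 1
  for (k in seq_len(horizon)) {
    v <- if (k <= qm) m[k] else 0
    for (i in seq_len(min(k, pa))) {
      prev <- if (k - i == 0L) psi0 else psi[k - i]
      v <- v - a[i] * prev
    }
    psi[k] <- v
  }
  se <- sqrt(sigma2 * cumsum(c(psi0, psi[-horizon])^2))

  e <- series_end(history)
  start <- .index_ym(.ym_index(e[1L], e[2L]) + 1L)
  .forecast_result(yy[n + seq_len(horizon)], se, start, history$name, level)
}

#' Published per-depth soil-moisture SARIMA models for the Xilingol site
#'
#' The fixed seasonal ARIMA equations published for the Xilingol kastanozem
#' site at 10, 40 and 100 cm, in the R sign convention (a printed factor
#' `(1 - c B)` on the moving-average side corresponds to an `ma` coefficient
#' of `-c` here). The 10 cm model is `(0,0,1)(0,1,1)[12]`; the 40 cm model is
#' read as AR(1) with MA(2) and seasonal MA(2) on one ordinary difference;
#' the 100 cm model is `(0,1,1)`. The published 200 cm equation does not
#' factor into the standard (AR)(SAR)(difference)(MA)(SMA) form and is not
#' shipped.
#'
#' @return named list of [sarima_spec()] objects, names `"10"`, `"40"`,
#'   `"100"` (depth in cm).
#' @export
published_sm_models <- function() {
  list(
    "10" = sarima_spec(c(0L, 0L, 1L), c(0L, 1L, 1L), 12L,
                       ma = -0.5852, sma = -0.7593),
    "40" = sarima_spec(c(1L, 1L, 2L), c(0L, 0L, 2L), 12L,
                       ar = 0.9869, ma = c(-1.0677, 0.2250),
                       sma = c(-0.4081, -0.2313)),
    "100" = sarima_spec(c(0L, 1L, 1L), c(0L, 0L, 0L), 12L, ma = 0.5308)
  )
}

#' One-line summary table of a fitted SARIMA model
#'
#' @param fitted a `sarima_fit`.
#' @param lags Ljung-Box lags for the residual check (default 12).
#' @return data frame with orders, AIC/BIC, sigma2 and the Ljung-Box
#'   p-value of the residuals.
#' @export
sarima_report <- function(fitted, lags = 12L) {
  s <- fitted$spec
  lb <- if (fitted$degenerate) NA_real_ else {
    df <- min(sarima_df(fitted), lags - 1L)
    ljung_box(sarima_residuals(fitted), lags = lags, fitted_df = df)$p_value
  }
  data.frame(
    p = s$order[1L], d = s$order[2L], q = s$order[3L],
    P = s$seasonal_order[1L], D = s$seasonal_order[2L], Q = s$seasonal_order[3L],
    period = s$period, sigma2 = s$sigma2, aic = s$aic, bic = s$bic,
    ljung_box_p = lb, degenerate = fitted$degenerate
  )
}
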