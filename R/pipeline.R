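# interception series with either a window-constant or per-month ICmax
.ic_series <- function(vcr, p, lai, icmax_mode, k) {
  if (icmax_mode == "window-max") {
    interception_series(vcr, p, interception_params(intercept_max(max(lai$values)), k))
  } else {
    check_aligned(vcr, p); check_aligned(vcr, lai)
    ic <- vapply(seq_along(p$values), function(t) {
      interception_flow(vcr$values[t], p$values[t],
                        interception_params(intercept_max(lai$values[t]), k))
    }, numeric(1L))
    monthly_series(ic, p$start, "ICstore", "mm/month")
  }
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("model A stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Hybrid water-balance soil-moisture forecast (Model A)
#'
#' Runs the full hybrid pipeline: (i) fill the vegetation coverage series
#' from NDVI where missing; (ii) forecast the four drivers (SE, P, LAI,
#' VCR) `horizon` months ahead with the automatic seasonal-ARIMA engine,
#' flooring physical drivers at 0 and clipping the coverage rate into
#' [0, 1]; (iii) compute the canopy interception of the forecast window
#' (ICmax from the forecast LAI, window maximum by default); (iv) form the
#' water-balance increment forecast; (v) estimate the per-depth coefficient
#' on the historical record (increment from historical drivers, ICmax from
#' the historical LAI window); (vi) iterate the depth recursion from the
#' last observed moisture at each depth.
#'
#' @param drivers historical [driver_set()] (VCR may be incomplete).
#' @param profile historical [sm_profile()] aligned with `drivers`.
#' @param horizon forecast length in months, `>= 1`.
#' @param precip_scale precipitation multiplier of [wb_config()].
#' @param k interception density-correction factor (default 1).
#' @param icmax_mode `"window-max"` (default) or `"per-month"`.
#' @param estimate_alpha jointly estimate the persistence coefficient
#'   (default `FALSE`, alpha fixed at 1).
#' @param level driver forecast interval level (recorded, default 0.95).
#' @return an object of class `model_a_result`: list with `forecast`
#'   (named list of per-depth `monthly_series`), `depth_models`,
#'   `driver_forecasts` (named list of `forecast_result`), `dbeta_forecast`,
#'   `ic_max` and `vcr_model`.
#' @export
model_a_pipeline <- function(drivers, profile, horizon,
                             precip_scale = 1 / 30, k = 1,
                             icmax_mode = c("window-max", "per-month"),
                             estimate_alpha = FALSE, level = 0.95) {
  icmax_mode <- match.arg(icmax_mode)
  if (!is.numeric(horizon) || horizon < 1L) {
    stop("model A stage 'setup': horizon must be >= 1", call. = FALSE)
  }
  horizon <- as.integer(horizon)
  check_aligned(drivers$p, profile$series[[1L]])
  cfg <- wb_config(precip_scale)

  drivers <- .stage("fill-vcr", fill_vcr(drivers))

  fc <- .stage("driver-forecast", {
    lapply(list(se = drivers$se, p = drivers$p, lai = drivers$lai,
                vcr = drivers$vcr),
           function(s) forecast_sarima(auto_fit(s), horizon, level))
  })
  clip01 <- function(v) pmin(pmax(v, 0), 1)
  p_f <- monthly_series(pmax(fc$p$point$values, 0), fc$p$point$start, "P", "mm/month")
  se_f <- monthly_series(pmax(fc$se$point$values, 0), fc$se$point$start, "SE", "mm/month")
  lai_f <- monthly_series(pmax(fc$lai$point$values, 0), fc$lai$point$start, "LAI", "m2/m2")
  vcr_f <- monthly_series(clip01(fc$vcr$point$values), fc$vcr$point$start, "VCR", "fraction")

  ic_f <- .stage("interception", .ic_series(vcr_f, p_f, lai_f, icmax_mode, k))
  dbeta_f <- .stage("delta-beta", monthly_series(
    delta_beta(p_f$values, se_f$values, ic_f$values, cfg),
    p_f$start, "dbeta", "dimensionless"))

  dbeta_h <- .stage("history-delta-beta", {
    ic_h <- .ic_series(drivers$vcr, drivers$p, drivers$lai, icmax_mode, k)
    monthly_series(delta_beta(drivers$p$values, drivers$se$values, ic_h$values, cfg),
                   drivers$p$start, "dbeta", "dimensionless")
  })

  depth_models <- .stage("depth-fit", {
    out <- lapply(seq_along(profile$depths), function(i) {
      fit_depth_model(profile$series[[i]], dbeta_h,
                      depth_cm = profile$depths[i],
                      estimate_alpha = estimate_alpha)
    })
    names(out) <- profile$depths
    out
  })

  forecast <- .stage("recursion", {
    out <- lapply(seq_along(profile$depths), function(i) {
      sm <- profile$series[[i]]
      forecast_recursive(sm$values[length(sm$values)], dbeta_f, depth_models[[i]])
    })
    names(out) <- profile$depths
    out
  })

  structure(list(forecast = forecast, depth_models = depth_models,
                 driver_forecasts = fc, dbeta_forecast = dbeta_f,
                 ic_max = if (icmax_mode == "window-max")
                   intercept_max(max(lai_f$values)) else NA_real_,
                 vcr_model = attr(drivers, "vcr_model")),
            class = "model_a_result")
}

#' @export
print.model_a_result <- function(x, ...) {
  g <- vapply(x$depth_models, function(m) m$gamma, numeric(1L))
  cat(sprintf("<model_a_result> depths (cm): %s\n gamma: %s\n",
              paste(names(x$forecast), collapse = ", "),
              paste(sprintf("%.4f", g), collapse = ", ")))
  invisible(x)
}

#' Per-depth seasonal-ARIMA soil-moisture forecast (Model B)
#'
#' The baseline forecaster: each depth's moisture series is fitted with the
#' automatic seasonal-ARIMA engine on its own history and forecast
#' `horizon` months ahead with Gaussian prediction intervals.
#'
#' @param profile historical [sm_profile()].
#' @param horizon forecast length in months, `>= 1`.
#' @param level interval coverage (default 0.95).
#' @return an object of class `model_b_result`: list with `forecast`
#'   (named list of per-depth point-forecast `monthly_series`), `intervals`
#'   (named list of `forecast_result`), `fits` and `reports` (per-depth
#'   [sarima_report()] rows).
#' @export
model_b_pipeline <- function(profile, horizon, level = 0.95) {
  if (!is.numeric(horizon) || horizon < 1L) stop("horizon must be >= 1", call. = FALSE)
  horizon <- as.integer(horizon)
  fits <- lapply(profile$series, auto_fit)
  fr <- lapply(fits, forecast_sarima, horizon = horizon, level = level)
  forecast <- lapply(fr, function(f) {
    monthly_series(pmax(f$point$values, 0), f$point$start,
                   f$point$name, "kg/m3")
  })
  reports <- do.call(rbind, lapply(fits, sarima_report))
  reports <- cbind(depth_cm = profile$depths, reports)
  rownames(reports) <- NULL
  structure(list(forecast = forecast, intervals = fr, fits = fits,
                 reports = reports),
            class = "model_b_result")
}

#' @export
print.model_b_result <- function(x, ...) {
  cat(sprintf("<model_b_result> depths (cm): %s\n",
              paste(names(x$forecast), collapse = ", ")))
  invisible(x)
}
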