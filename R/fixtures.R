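#' Published driver forecasts for the Xilingol site (Apr 2022 - Dec 2023)
#'
#' The 21 months of seasonal-ARIMA driver forecasts (soil evaporation SE,
#' precipitation P, LAI and vegetation coverage rate VCR) published for the
#' Xilingol League kastanozem site, together with the published canopy
#' interception (`IC_ref`) and water-balance increment (`dbeta_ref`)
#' computed from them. Driver values are printed to 4 decimals, so
#' recomputing IC and the increment from this table agrees with the
#' reference columns to about one unit in the fourth decimal.
#'
#' @return data frame with columns `year, month, SE, P, LAI, VCR, IC_ref,
#'   dbeta_ref`.
#' @examples
#' fx <- xilingol_forecast_drivers()
#' nrow(fx)          # 21
#' max(fx$LAI)       # 0.983 (August canopy peak)
#' @export
xilingol_forecast_drivers <- function() {
  utils::read.csv(system.file("extdata", "xilingol_forecast_drivers.csv",
                              package = "soilwb", mustWork = TRUE))
}

#' Published driver forecasts as aligned monthly series
#'
#' Same content as [xilingol_forecast_drivers()], packaged as
#' `monthly_series` objects for direct use with [interception_series()] and
#' [delta_beta_series()]. NDVI is not part of the published forecast table
#' and is returned as `NA` placeholders.
#'
#' @return a [driver_set()] spanning 2022-04 to 2023-12.
#' @export
xilingol_forecast_driver_set <- function() {
  fx <- xilingol_forecast_drivers()
  start <- c(fx$year[1L], fx$month[1L])
  driver_set(
    p    = monthly_series(fx$P, start, "P", "mm/month"),
    se   = monthly_series(fx$SE, start, "SE", "mm/month"),
    ndvi = monthly_series(rep(NA_real_, nrow(fx)), start, "NDVI",
                          "dimensionless", allow_na = TRUE),
    lai  = monthly_series(fx$LAI, start, "LAI", "m2/m2"),
    vcr  = monthly_series(fx$VCR, start, "VCR", "fraction")
  )
}

#' Published water-balance soil-moisture predictions for the Xilingol site
#'
#' The 21 months (Apr 2022 - Dec 2023) of per-depth soil-moisture
#' predictions published for the Xilingol site from the depth-parameter
#' water-balance recursion, with the published depth coefficients attached
#' as attribute `gamma` (`-0.1069, -0.1357, -0.0652, -0.0018` at 10, 40,
#' 100, 200 cm).
#'
#' @return data frame with columns `year, month, SM10, SM40, SM100, SM200`.
#' @export
xilingol_wb_predictions <- function() {
  df <- utils::read.csv(system.file("extdata", "xilingol_wb_predictions.csv",
                                    package = "soilwb", mustWork = TRUE))
  attr(df, "gamma") <- c("10" = -0.1069, "40" = -0.1357,
                         "100" = -0.0652, "200" = -0.0018)
  df
}
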