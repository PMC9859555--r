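Package: soilwb
Title: Soil Moisture Forecasting from a Water-Balance Recursion and Seasonal ARIMA Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monthly soil-moisture forecasting at multiple depths for semi-arid
    grassland sites. Combines a simplified soil-vegetation-atmosphere water
    balance (precipitation, soil evaporation and LAI-based canopy interception)
    with a per-depth recursive update whose depth coefficient is estimated by
    regression, and a seasonal ARIMA engine with automatic order selection used
    both to forecast the meteorological/vegetation drivers and as a standalone
    baseline forecaster. Includes NDVI-to-vegetation-cover polynomial
    regression, forecast error metrics (MSE, RMSE, MAE, MAPE), a train/test
    evaluation protocol comparing the hybrid and baseline models by depth, and
    a synthetic-site generator emulating a temperate semi-arid monthly climate
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
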