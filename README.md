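# soilwb

Monthly soil-moisture forecasting at multiple depths for semi-arid grassland
sites, built around two complementary forecasters and the protocol for
comparing them:

* **Hybrid water-balance model (model A).** A simplified
  soil–vegetation–atmosphere balance gives the monthly moisture increment
  `Δβ_t = s·P_t − SE_t − IC_t` (precipitation, soil evaporation, canopy
  interception; runoff and groundwater exchange assumed zero; `s` defaults
  to 1/30, the scale that reproduces the published worked examples).
  Interception follows `IC = c_p · ICmax · (1 − exp(−k·P/ICmax))` with
  `ICmax = 0.935 + 0.498·LAI − 0.00575·LAI²`, and vegetation cover `c_p` is
  filled from NDVI by polynomial regression where unobserved. Moisture at
  depth `h` then evolves as `β_{h,t+1} = α·β_{h,t} + γ_h·Δβ_t`, with the
  depth coefficient `γ_h` estimated from the site history and the drivers
  extended into the future by seasonal-ARIMA forecasts.
* **Seasonal ARIMA baseline (model B).** Automatic order selection (KPSS
  differencing, STL seasonal-strength heuristic, stepwise AIC search over
  `(p,q) ≤ 5`, `(P,Q) ≤ 2`, period 12) fitted directly to each depth's
  moisture series, with Gaussian prediction intervals and Ljung–Box
  residual diagnostics.

The package also provides the month-indexed series container and wide-CSV
site format, forecast error metrics (MSE/RMSE/MAE/MAPE) with a train/test
splitter and a per-depth model-comparison table, a synthetic semi-arid site
generator for end-to-end testing, fixed published models that can be applied
to new history without re-estimation, and a command-line interface.

## Worked example

Reproducing the published interception/water-balance worked examples from
the driver-forecast table shipped with the package:

```r
library(soilwb)

ds <- xilingol_forecast_driver_set()        # SE, P, LAI, VCR, 2022-04..2023-12
ic_max <- window_ic_max(ds$lai)             # ICmax at the August LAI peak
round(ic_max, 3)
#> [1] 1.419

db <- delta_beta_series(ds, interception_params(ic_max, k = 1), wb_config(1/30))
head(as.data.frame(db), 4)
#>   year month     value
#> 1 2022     4 -10.86140
#> 2 2022     5 -16.21774
#> 3 2022     6 -20.67087
#> 4 2022     7 -24.36731
```

The increments match the published column to the printed four decimals
(April, a dry month, is exactly `−SE`). Estimating depth coefficients on a
synthetic site generated by the model's own dynamics (true values −0.1069,
−0.1357, −0.0652, −0.0018):

```r
site <- generate_site(site_scenario(years = 9, seed = 3))
res <- model_a_pipeline(site$drivers, site$profile, horizon = 12)
t(sapply(res$depth_models, function(m) round(c(gamma = m$gamma, p = m$gamma_p), 4)))
#>       gamma p
#> 10  -0.1075 0
#> 40  -0.1328 0
#> 100 -0.0651 0
#> 200 -0.0021 0
```

Comparing the two forecasters on a site whose 10 cm layer follows its own
seasonal process while deeper layers follow the balance recursion (108
training months, 24 test months):

```r
sc <- site_scenario(years = 11, seed = 42,
                    process = c("sarima", "recursion", "recursion", "recursion"))
site <- generate_site(sc)
# split at 2021-01, forecast the test window with both models, then:
tab[tab$metric == "rmse", ]
#>    metric depth_cm model     value is_best
#> 1    rmse       10     A 4.6894472   FALSE
#> 2    rmse       10     B 0.8456999    TRUE
#> 9    rmse       40     A 5.6189711   FALSE
#> 10   rmse       40     B 4.0255212    TRUE
#> 17   rmse      100     A 3.9947077    TRUE
#> 18   rmse      100     B 5.6943579   FALSE
#> 25   rmse      200     A 0.2485994    TRUE
#> 26   rmse      200     B 0.4046309   FALSE
```

The baseline wins on the layer governed by surface periodicity; the hybrid
model wins on the deep recursion-driven layers (at 40 cm the two sit on a
common noise-accumulation error floor — see the methods vignette).

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "soilwb", package = "soilwb"))')
$CLI simulate   --years 10 --seed 1 --output runs/site        # site.csv + truth.csv
$CLI forecast-a --input runs/site/site.csv --output runs/a --horizon 21
$CLI forecast-b --input runs/site/site.csv --output runs/b --horizon 21
$CLI compare    --input runs/site/site.csv --output runs/cmp --split 2021-1
```

Commands read a flat `key = value` config file via `--config`, with
command-line flags taking precedence.

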