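#' Scenario for the synthetic semi-arid site generator
#'
#' Describes a temperate semi-arid monthly climate of the kind the
#' water-balance forecaster targets: about 340 mm of annual precipitation of
#' which roughly 74.4% falls June-September (with genuinely dry winter
#' months), a soil-evaporation cycle peaking in July over a range of about
#' 0.3-39 mm/month, a grassland LAI cycle peaking in August, NDVI as a
#' monotone map of LAI, coverage rate from NDVI via the published cubic, and
#' multi-depth soil moisture generated by the depth recursion itself with
#' known parameters plus Gaussian noise.
#'
#' Default depth coefficients are the published Xilingol values
#' (-0.1069, -0.1357, -0.0652, -0.0018 at 10/40/100/200 cm) and the default
#' noise standard deviations decrease with depth, mimicking the observed
#' ordering of variability (deep moisture is nearly constant).
#'
#' @param years record length in years, `>= 3` (default 10).
#' @param start first month, default `c(2012, 1)`.
#' @param annual_p mean annual precipitation, mm (default 340).
#' @param summer_p_fraction share of precipitation falling June-September
#'   (default 0.744).
#' @param se_peak July peak of mean soil evaporation, mm/month (default 27).
#' @param se_min winter minimum of mean soil evaporation (default 0.5).
#' @param lai_range `c(min, max)` of the seasonal LAI cycle (default
#'   `c(0.6, 1.0)`).
#' @param depths depths in cm (default `c(10, 40, 100, 200)`).
#' @param gamma per-depth coefficients (same length as `depths`).
#' @param alpha per-depth persistence coefficients (default all 1).
#' @param noise_sd per-depth moisture noise SD, kg/m3 (default
#'   `c(0.8, 0.6, 0.5, 0.05)`).
#' @param sm_init per-depth initial moisture, kg/m3 (defaults near observed
#'   depth means: 14.57, 42.38, 55.35, 167.22).
#' @param process per-depth generating process: `"recursion"` (the depth
#'   recursion; default) or `"sarima"` (a seasonal autoregressive process
#'   independent of the drivers, used to emulate a shallow layer governed by
#'   its own periodicity).
#' @param misspecified add an AR(1) disturbance (coefficient 0.5) to the
#'   recursion noise to probe robustness to model misspecification.
#' @param precip_scale passed to [wb_config()] when generating the
#'   increment (default 1/30).
#' @param seed RNG seed (default 1).
#' @return an object of class `site_scenario`.
#' @export
site_scenario <- function(years = 10L, start = c(2012L, 1L),
                          annual_p = 340, summer_p_fraction = 0.744,
                          se_peak = 27, se_min = 0.5,
                          lai_range = c(0.6, 1.0),
                          depths = c(10L, 40L, 100L, 200L),
                          gamma = c(-0.1069, -0.1357, -0.0652, -0.0018),
                          alpha = rep(1, length(depths)),
                          noise_sd = c(0.8, 0.6, 0.5, 0.05),
                          sm_init = c(14.57, 42.38, 55.35, 167.22),
                          process = rep("recursion", length(depths)),
                          misspecified = FALSE,
                          precip_scale = 1 / 30,
                          seed = 1L) {
  if (years < 3L) stop("years must be >= 3", call. = FALSE)
  if (summer_p_fraction <= 0 || summer_p_fraction >= 1) {
    stop("summer_p_fraction must be in (0, 1)", call. = FALSE)
  }
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  k <- length(depths)
  if (length(gamma) != k || length(alpha) != k || length(noise_sd) != k ||
      length(sm_init) != k || length(process) != k) {
    stop("gamma, alpha, noise_sd, sm_init and process must match depths",
         call. = FALSE)
  }
  if (!all(process %in% c("recursion", "sarima"))) {
    stop("process entries must be 'recursion' or 'sarima'", call. = FALSE)
  }
  structure(list(years = as.integer(years), start = as.integer(start),
                 annual_p = annual_p, summer_p_fraction = summer_p_fraction,
                 se_peak = se_peak, se_min = se_min, lai_range = lai_range,
                 depths = as.integer(depths), gamma = gamma, alpha = alpha,
                 noise_sd = noise_sd, sm_init = sm_init, process = process,
                 misspecified = misspecified, precip_scale = precip_scale,
                 seed = as.integer(seed)),
            class = "site_scenario")
}

# unconditional monthly mean precipitation implied by the scenario
.monthly_p_means <- function(sc) {
  summer <- c(0, 0, 0, 0, 0, 0.22, 0.28, 0.28, 0.22, 0, 0, 0)
  off <- c(0.04, 0.05, 0.08, 0.14, 0.22, 0, 0, 0, 0, 0.22, 0.14, 0.11)
  sc$annual_p * (sc$summer_p_fraction * summer +
                   (1 - sc$summer_p_fraction) * off)
}

# per-month probability of an entirely dry month
.dry_month_prob <- c(0.35, 0.35, 0.25, 0.20, 0.05, 0, 0, 0, 0, 0.05, 0.25, 0.35)

#' Generate a synthetic site record
#'
#' Draws a full multi-year site record from a [site_scenario()]:
#' precipitation as a per-month zero-inflated gamma (dry-season months can
#' be exactly 0) whose unconditional monthly means follow the scenario's
#' annual total and summer share; soil evaporation and LAI as phase-locked
#' seasonal cycles (July and August peaks) with multiplicative and additive
#' noise; NDVI as the monotone map `0.6 LAI - 0.05`; coverage rate from
#' NDVI via the published cubic; and per-depth soil moisture from the depth
#' recursion (or a seasonal AR process where the scenario says so) with the
#' scenario's parameters.
#'
#' @param scenario a [site_scenario()].
#' @return list with `drivers` (a [driver_set()] with complete VCR),
#'   `profile` (an [sm_profile()]) and `truth` (data frame of the
#'   generating parameters per depth, plus attributes `ic_max` and `dbeta`,
#'   the increment series the moisture was generated from).
#' @examples
#' site <- generate_site(site_scenario(years = 4, seed = 7))
#' length(site$drivers$p)  # 48
#' @export
generate_site <- function(scenario) {
  stopifnot(inherits(scenario, "site_scenario"))
  set.seed(scenario$seed)
  n <- scenario$years * 12L
  month <- ((scenario$start[2L] - 1L + seq_len(n) - 1L) %% 12L) + 1L
  mu <- .monthly_p_means(scenario)[month]
  p0 <- .dry_month_prob[month]

  wet <- stats::runif(n) >= p0
  shape <- 1.5
  p <- ifelse(wet & mu > 0,
              stats::rgamma(n, shape = shape,
                            scale = pmax(mu / pmax(1 - p0, 1e-9), 1e-9) / shape),
              0)

  se_mean <- scenario$se_min + (scenario$se_peak - scenario$se_min) *
    0.5 * (1 + cos(2 * pi * (month - 7) / 12))
  se <- pmax(se_mean * exp(stats::rnorm(n, 0, 0.15)), 0.05)

  lai_mean <- scenario$lai_range[1L] +
    diff(scenario$lai_range) * 0.5 * (1 + cos(2 * pi * (month - 8) / 12))
  lai <- pmax(lai_mean + stats::rnorm(n, 0, 0.02), 0.05)

  ndvi <- 0.6 * lai - 0.05
  vcr <- predict_vcr(vcr_published_model(), ndvi)

  start <- scenario$start
  drivers <- driver_set(
    p    = monthly_series(p, start, "P", "mm/month"),
    se   = monthly_series(se, start, "SE", "mm/month"),
    ndvi = monthly_series(ndvi, start, "NDVI", "dimensionless"),
    lai  = monthly_series(lai, start, "LAI", "m2/m2"),
    vcr  = monthly_series(vcr, start, "VCR", "fraction")
  )

  ic_max <- intercept_max(max(lai))
  dbeta <- delta_beta_series(drivers, interception_params(ic_max),
                             wb_config(scenario$precip_scale))

  series <- vector("list", length(scenario$depths))
  for (i in seq_along(scenario$depths)) {
    sdv <- scenario$noise_sd[i]
    if (scenario$process[i] == "sarima") {
      # shallow layer driven by its own seasonality, not by the balance
      seas <- 0.20 * scenario$sm_init[i] * cos(2 * pi * (month - 7) / 12)
      ar <- stats::filter(stats::rnorm(n, 0, max(sdv, 0.4)), 0.6,
                          method = "recursive")
      sm <- pmax(scenario$sm_init[i] + seas + as.numeric(ar), 0.5)
    } else {
      eps <- stats::rnorm(n, 0, sdv)
      if (scenario$misspecified) {
        eps <- as.numeric(stats::filter(eps, 0.5, method = "recursive"))
      }
      sm <- numeric(n)
      sm[1L] <- scenario$sm_init[i]
      for (t in 2:n) {
        sm[t] <- max(scenario$alpha[i] * sm[t - 1L] +
                       scenario$gamma[i] * dbeta$values[t - 1L] + eps[t], 0.01)
      }
    }
    series[[i]] <- monthly_series(sm, start, paste0("SM", scenario$depths[i]),
                                  "kg/m3")
  }
  names(series) <- scenario$depths

  truth <- data.frame(depth_cm = scenario$depths, gamma = scenario$gamma,
                      alpha = scenario$alpha, noise_sd = scenario$noise_sd,
                      process = scenario$process, seed = scenario$seed)
  attr(truth, "ic_max") <- ic_max
  list(drivers = drivers, profile = sm_profile(series), truth = truth,
       dbeta = dbeta)
}
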