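#' Maximum canopy interception from leaf area index
#'
#' Empirical quadratic relating the maximum interception storage of the
#' canopy (mm) to LAI:
#' `ICmax = 0.935 + 0.498 LAI - 0.00575 LAI^2`.
#' The quadratic is increasing over the whole physically relevant LAI range
#' (its vertex sits near LAI 43.3, far beyond grassland canopies).
#'
#' @param lai leaf area index, m2/m2, nonnegative.
#' @return maximum interception in mm (vectorised).
#' @examples
#' intercept_max(0.983)  # 1.419 (grassland canopy near peak season)
#' @export
intercept_max <- function(lai) {
  if (any(!is.finite(lai)) || any(lai < 0)) {
    stop("LAI must be finite and nonnegative", call. = FALSE)
  }
  0.935 + 0.498 * lai - 0.00575 * lai^2
}

#' Canopy interception parameters
#'
#' @param ic_max maximum interception storage, mm, `>= 0`.
#' @param k vegetation-density correction factor, `> 0`. Defaults to 1: for
#'   this grassland system density effects are folded into the coverage rate
#'   and LAI, and k is kept as an explicit tuning knob rather than estimated.
#' @return an object of class `interception_params`.
#' @export
interception_params <- function(ic_max, k = 1) {
  if (!is.finite(ic_max) || ic_max < 0) stop("ic_max must be >= 0", call. = FALSE)
  if (!is.finite(k) || k <= 0) stop("k must be > 0", call. = FALSE)
  structure(list(ic_max = ic_max, k = k), class = "interception_params")
}

#' Monthly canopy interception flow
#'
#' Saturating interception model: the canopy of a fully covered plot catches
#' at most `ic_max` mm of a month's rainfall, approached exponentially as
#' precipitation grows, and the plot-scale flow is scaled by the vegetation
#' coverage rate:
#' `IC = cp * ICmax * (1 - exp(-k P / ICmax))`.
#' Zero precipitation or zero coverage gives zero interception, and the flow
#' is nondecreasing in each of `cp`, `p` and `k`.
#'
#' @param cp vegetation coverage rate in `[0, 1]`.
#' @param p precipitation, mm/month, `>= 0`.
#' @param params an [interception_params()].
#' @return interception flow, mm/month (vectorised over `cp` and `p`).
#' @examples
#' interception_flow(0.2814, 83.1367, interception_params(1.419))
#' @export
interception_flow <- function(cp, p, params) {
  stopifnot(inherits(params, "interception_params"))
  if (any(!is.finite(cp)) || any(cp < 0) || any(cp > 1)) {
    stop("coverage rate cp must lie in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("precipitation must be finite and >= 0", call. = FALSE)
  }
  if (params$ic_max == 0) return(rep(0, max(length(cp), length(p))))
  cp * params$ic_max * (1 - exp(-params$k * p / params$ic_max))
}

#' Interception flow for aligned monthly series
#'
#' Elementwise [interception_flow()] over aligned coverage-rate and
#' precipitation series.
#'
#' @param vcr coverage-rate `monthly_series` (fraction, complete).
#' @param p precipitation `monthly_series` (mm/month).
#' @param params an [interception_params()].
#' @return a `monthly_series` named `ICstore`, unit mm/month.
#' @export
interception_series <- function(vcr, p, params) {
  check_aligned(vcr, p)
  if (anyNA(vcr$values)) stop("VCR series has missing cells; fill it first", call. = FALSE)
  monthly_series(interception_flow(vcr$values, p$values, params),
                 p$start, "ICstore", "mm/month")
}

#' Maximum interception for a window of LAI values
#'
#' The default (`"window-max"`) evaluates [intercept_max()] once at the
#' largest LAI of the window, giving a single canopy capacity for the whole
#' forecast period; `"per-month"` evaluates it at each month's LAI instead.
#' The window-max convention treats ICmax as a property of the fully
#' developed canopy rather than of its instantaneous state.
#'
#' @param lai `monthly_series` of LAI.
#' @param mode `"window-max"` (default) or `"per-month"`.
#' @return scalar (window-max) or numeric vector (per-month) of ICmax, mm.
#' @export
window_ic_max <- function(lai, mode = c("window-max", "per-month")) {
  mode <- match.arg(mode)
  if (mode == "window-max") intercept_max(max(lai$values)) else intercept_max(lai$values)
}
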