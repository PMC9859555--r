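#' Polynomial regression of vegetation coverage rate on NDVI
#'
#' Fits an ordinary least-squares polynomial `VCR ~ NDVI + NDVI^2 + ...` of
#' the requested degree. VCR is observed only on short field campaigns while
#' NDVI is available for the whole record, so the fitted polynomial is used
#' to fill the VCR series ([fill_vcr()]). Degrees 1 to 3 are supported;
#' the fit reports adjusted R-squared, the overall F-test p-value and
#' per-coefficient two-sided t-test p-values so the selection rule of
#' [select_vcr_model()] can be applied.
#'
#' @param ndvi,vcr paired numeric observations (same length).
#' @param degree polynomial degree, 1, 2 or 3.
#' @return an object of class `vcr_poly` with fields `degree`,
#'   `coefficients` (intercept first), `adj_r2`, `f_test_p`, `coef_p`.
#' @examples
#' nd <- seq(0.05, 0.6, length.out = 21)
#' fit <- fit_vcr_polynomial(nd, 0.2 + 0.5 * nd, degree = 1)
#' fit$coefficients  # ~ (0.2, 0.5)
#' @export
fit_vcr_polynomial <- function(ndvi, vcr, degree) {
  if (!degree %in% 1:3) stop("degree must be 1, 2 or 3", call. = FALSE)
  ok <- !is.na(ndvi) & !is.na(vcr)
  ndvi <- as.numeric(ndvi[ok]); vcr <- as.numeric(vcr[ok])
  if (length(ndvi) < degree + 2L) {
    stop("need at least degree + 2 paired observations", call. = FALSE)
  }
  if (length(unique(ndvi)) < degree + 1L) {
    stop("singular fit: too few distinct NDVI values for degree ", degree,
         call. = FALSE)
  }
  X <- stats::poly(ndvi, degree = degree, raw = TRUE)
  fit <- stats::lm(vcr ~ X)
  if (anyNA(stats::coef(fit))) stop("singular polynomial fit", call. = FALSE)
  # suppress the "essentially perfect fit" note on noise-free inputs
  sm <- suppressWarnings(summary(fit))
  fp <- if (is.null(sm$fstatistic)) NA_real_ else
    unname(stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
                     lower.tail = FALSE))
  structure(
    list(degree = degree,
         coefficients = unname(stats::coef(fit)),
         adj_r2 = sm$adj.r.squared,
         f_test_p = fp,
         coef_p = unname(sm$coefficients[, 4L]),
         n = length(ndvi)),
    class = "vcr_poly"
  )
}

#' @export
print.vcr_poly <- function(x, ...) {
  cat(sprintf("<vcr_poly> degree %d, adj R^2 = %.3f\n coefficients: %s\n",
              x$degree, x$adj_r2,
              paste(signif(x$coefficients, 4), collapse = ", ")))
  invisible(x)
}

#' Select the NDVI-to-VCR polynomial degree
#'
#' Fits degrees 1-3 and returns the candidate with the largest adjusted
#' R-squared among those whose coefficients are all significant at the 0.05
#' level (the starring convention of the usual regression comparison table).
#' If no candidate passes the significance rule, the highest-adjusted-R2
#' model is returned with `selected_by_rule = FALSE`. The full comparison is
#' kept in the `comparison` attribute (one row per degree), exportable with
#' [vcr_comparison_table()].
#'
#' @inheritParams fit_vcr_polynomial
#' @param alpha per-coefficient significance threshold (default 0.05).
#' @return a `vcr_poly` with extra fields `selected_by_rule` and `comparison`.
#' @export
select_vcr_model <- function(ndvi, vcr, alpha = 0.05) {
  fits <- lapply(1:3, function(d) fit_vcr_polynomial(ndvi, vcr, d))
  all_sig <- vapply(fits, function(f) all(f$coef_p < alpha), logical(1L))
  adj <- vapply(fits, function(f) f$adj_r2, numeric(1L))
  comparison <- data.frame(
    degree = 1:3, adj_r2 = adj,
    f_test_p = vapply(fits, function(f) f$f_test_p, numeric(1L)),
    all_coef_significant = all_sig
  )
  pick <- if (any(all_sig)) which(all_sig)[which.max(adj[all_sig])] else which.max(adj)
  out <- fits[[pick]]
  out$selected_by_rule <- any(all_sig)
  out$comparison <- comparison
  out
}

#' Export the degree-comparison table of a selected VCR model
#' @param model result of [select_vcr_model()].
#' @param path optional CSV path; if given the table is also written there.
#' @return the comparison data frame.
#' @export
vcr_comparison_table <- function(model, path = NULL) {
  if (is.null(model$comparison)) stop("model carries no comparison table", call. = FALSE)
  if (!is.null(path)) utils::write.csv(model$comparison, path, row.names = FALSE)
  model$comparison
}

#' Published cubic NDVI-to-VCR model for the Xilingol site
#'
#' The fixed cubic `VCR = 0.008 - 0.894 NDVI + 5.827 NDVI^2 - 5.778 NDVI^3`
#' selected for the Xilingol League kastanozem site, shipped as a constant so
#' the pipeline can run exactly as published when no local VCR observations
#' are available to refit it.
#'
#' @return a `vcr_poly` with the fixed coefficients (no fit statistics).
#' @export
vcr_published_model <- function() {
  structure(
    list(degree = 3L,
         coefficients = c(0.008, -0.894, 5.827, -5.778),
         adj_r2 = NA_real_, f_test_p = NA_real_,
         coef_p = rep(NA_real_, 4L), n = NA_integer_),
    class = "vcr_poly"
  )
}

#' Predict vegetation coverage rate from NDVI
#'
#' Evaluates the polynomial and, by default, clips the result into `[0, 1]`:
#' a coverage rate is a physical fraction, and extrapolating a cubic slightly
#' outside the NDVI range it was fitted on can otherwise produce values just
#' below 0. Set `clip = FALSE` to obtain the raw polynomial value.
#'
#' @param model a `vcr_poly`.
#' @param ndvi numeric vector of NDVI values.
#' @param clip clip predictions into `[0, 1]` (default `TRUE`).
#' @return numeric vector of predicted coverage rates.
#' @examples
#' predict_vcr(vcr_published_model(), 0)  # 0.008
#' @export
predict_vcr <- function(model, ndvi, clip = TRUE) {
  co <- model$coefficients
  # Horner evaluation, intercept-first coefficient order
  y <- rep(co[length(co)], length(ndvi))
  for (i in seq(length(co) - 1L, 1L)) y <- y * ndvi + co[i]
  if (clip) y <- pmin(pmax(y, 0), 1)
  y
}

#' Fill missing vegetation-coverage cells from NDVI
#'
#' Replaces `NA` cells of the VCR series with polynomial predictions from the
#' aligned NDVI series. If `model` is `NULL`, a model is chosen by
#' [select_vcr_model()] on the observed (NDVI, VCR) pairs when at least six
#' are available, and the published Xilingol cubic
#' ([vcr_published_model()]) is used otherwise.
#'
#' @param drivers a [driver_set()].
#' @param model optional `vcr_poly` to use instead of fitting.
#' @return a `driver_set` whose VCR series is complete; the model used is
#'   attached as attribute `vcr_model`.
#' @export
fill_vcr <- function(drivers, model = NULL) {
  vcr <- drivers$vcr$values
  if (!anyNA(vcr) && is.null(model)) return(drivers)
  if (is.null(model)) {
    obs <- !is.na(vcr)
    model <- if (sum(obs) >= 6L) {
      select_vcr_model(drivers$ndvi$values[obs], vcr[obs])
    } else {
      vcr_published_model()
    }
  }
  miss <- is.na(vcr)
  vcr[miss] <- predict_vcr(model, drivers$ndvi$values[miss])
  out <- driver_set(drivers$p, drivers$se, drivers$ndvi, drivers$lai,
                    monthly_series(vcr, drivers$p$start, "VCR", "fraction"))
  attr(out, "vcr_model") <- model
  out
}
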