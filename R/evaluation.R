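#' Forecast error metrics
#'
#' Computes the four standard metrics over aligned actual and predicted
#' series: MSE, RMSE (its square root), MAE, and MAPE in percent
#' (`100/n * sum(|(pred - actual)/actual|)`). MAPE is undefined when any
#' actual value is zero; in that case it is reported `NA` with a warning
#' while the other metrics are still computed, so the sample size `n` is
#' never silently changed.
#'
#' @param actual,predicted aligned `monthly_series` of equal length, or
#'   plain numeric vectors of equal length.
#' @return an object of class `error_report`: list with `n`, `mse`, `rmse`,
#'   `mae`, `mape`.
#' @examples
#' score(c(1, 2), c(2, 4))  # MSE 2.5, RMSE 1.58, MAE 1.5, MAPE 100
#' @export
score <- function(actual, predicted) {
  if (inherits(actual, "monthly_series")) {
    check_aligned(actual, predicted)
    actual <- actual$values; predicted <- predicted$values
  }
  if (length(actual) != length(predicted) || length(actual) < 1L) {
    stop("actual and predicted must be nonempty and of equal length", call. = FALSE)
  }
  e <- predicted - actual
  n <- length(e)
  mse <- mean(e^2)
  mape <- if (any(actual == 0)) {
    warning("MAPE undefined: actual series contains zeros; reported NA",
            call. = FALSE)
    NA_real_
  } else {
    100 * mean(abs(e / actual))
  }
  structure(list(n = n, mse = mse, rmse = sqrt(mse), mae = mean(abs(e)),
                 mape = mape),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> n = %d  MSE %.4f  RMSE %.4f  MAE %.4f  MAPE %s\n",
              x$n, x$mse, x$rmse, x$mae,
              if (is.na(x$mape)) "NA" else sprintf("%.4f%%", x$mape)))
  invisible(x)
}

#' Compare forecast models across depths
#'
#' Scores every (model, depth) forecast against the observed profile and
#' builds the long comparison table `metric x depth x model`, flagging the
#' minimum error per (metric, depth) cell. Ties within `tol` are all
#' flagged.
#'
#' @param actual_profile an [sm_profile()] of observed test-window moisture.
#' @param forecasts named list (one element per model) of named lists of
#'   forecast `monthly_series` keyed by depth (`"10"`, `"40"`, ...); every
#'   model must supply every depth of `actual_profile`.
#' @param tol tie tolerance on the error values (default `1e-12`).
#' @return data frame with columns `metric`, `depth_cm`, `model`, `value`,
#'   `is_best`.
#' @export
compare_models <- function(actual_profile, forecasts, tol = 1e-12) {
  depths <- as.character(actual_profile$depths)
  for (mod in names(forecasts)) {
    missing_d <- setdiff(depths, names(forecasts[[mod]]))
    if (length(missing_d)) {
      stop("model '", mod, "' is missing forecasts for depth(s) ",
           paste(missing_d, collapse = ", "), " cm", call. = FALSE)
    }
  }
  metrics <- c("rmse", "mse", "mae", "mape")
  rows <- list()
  for (d in depths) {
    reports <- lapply(forecasts, function(f) {
      score(actual_profile$series[[d]], f[[d]])
    })
    for (met in metrics) {
      vals <- vapply(reports, function(r) r[[met]], numeric(1L))
      best <- if (all(is.na(vals))) rep(NA, length(vals)) else
        vals <= min(vals, na.rm = TRUE) + tol
      rows[[length(rows) + 1L]] <- data.frame(
        metric = met, depth_cm = as.integer(d), model = names(forecasts),
        value = unname(vals), is_best = unname(best), row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
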