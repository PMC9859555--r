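#' Month-indexed time series
#'
#' `monthly_series()` builds the basic container used throughout soilwb: a
#' gap-free sequence of monthly values of one site variable, tagged with a
#' name and a physical unit. All model arithmetic in the package is monthly,
#' so the index is a (year, month) pair rather than a day-resolved timestamp.
#'
#' Values must be finite. Series carrying a mass or depth-of-water unit
#' (`"kg/m3"`, `"mm/month"`) must be nonnegative. Missing values (`NA`) are
#' only permitted when `allow_na = TRUE`; in practice this is used for the
#' vegetation coverage rate, the one variable that is routinely observed on a
#' short sub-window and later filled by regression on NDVI.
#'
#' @param values numeric vector, one value per consecutive calendar month.
#' @param start length-2 integer vector `c(year, month)` of the first value.
#' @param name variable identifier (e.g. `"P"`, `"SM40"`).
#' @param unit one of `"mm/month"`, `"kg/m3"`, `"dimensionless"`,
#'   `"m2/m2"`, `"fraction"`.
#' @param allow_na allow `NA` cells (vegetation coverage rate only).
#' @return an object of class `monthly_series`.
#' @examples
#' p <- monthly_series(c(0, 12.5, 60.2), c(2020, 1), "P", "mm/month")
#' series_end(p)  # 2020 3
#' @export
monthly_series <- function(values, start, name = "x", unit = "dimensionless",
                           allow_na = FALSE) {
  units_ok <- c("mm/month", "kg/m3", "dimensionless", "m2/m2", "fraction")
  if (!unit %in% units_ok) {
    stop("unknown unit '", unit, "'; expected one of: ",
         paste(units_ok, collapse = ", "), call. = FALSE)
  }
  values <- as.numeric(values)
  if (length(values) < 1L) stop("a monthly series needs at least one value", call. = FALSE)
  start <- as.integer(start)
  if (length(start) != 2L || is.na(start[1L]) || start[2L] < 1L || start[2L] > 12L) {
    stop("start must be c(year, month) with month in 1..12", call. = FALSE)
  }
  if (anyNA(values)) {
    if (!allow_na) stop("series '", name, "' contains missing values", call. = FALSE)
  }
  if (any(!is.finite(values[!is.na(values)]))) {
    stop("series '", name, "' contains non-finite values", call. = FALSE)
  }
  if (unit %in% c("mm/month", "kg/m3") && any(values < 0, na.rm = TRUE)) {
    stop("series '", name, "' (", unit, ") has negative values", call. = FALSE)
  }
  structure(
    list(name = name, unit = unit, start = start, values = values),
    class = "monthly_series"
  )
}

# linear month index: Jan of year y is y*12 + 0
.ym_index <- function(year, month) as.integer(year) * 12L + (as.integer(month) - 1L)

.index_ym <- function(idx) c(idx %/% 12L, idx %% 12L + 1L)

.ym_label <- function(year, month) sprintf("%04d-%02d", year, month)

#' @export
length.monthly_series <- function(x) length(x$values)

#' Last (year, month) of a series
#' @param x a `monthly_series`.
#' @return integer `c(year, month)`.
#' @export
series_end <- function(x) {
  .index_ym(.ym_index(x$start[1L], x$start[2L]) + length(x$values) - 1L)
}

#' Month index of a series as a two-column matrix
#' @param x a `monthly_series`.
#' @return integer matrix with columns `year`, `month`.
#' @export
series_months <- function(x) {
  idx <- .ym_index(x$start[1L], x$start[2L]) + seq_along(x$values) - 1L
  cbind(year = idx %/% 12L, month = idx %% 12L + 1L)
}

#' @export
print.monthly_series <- function(x, ...) {
  e <- series_end(x)
  cat(sprintf("<monthly_series> %s [%s] %s .. %s (n = %d)\n",
              x$name, x$unit,
              .ym_label(x$start[1L], x$start[2L]),
              .ym_label(e[1L], e[2L]), length(x$values)))
  invisible(x)
}

#' @export
as.data.frame.monthly_series <- function(x, ...) {
  ym <- series_months(x)
  data.frame(year = ym[, 1L], month = ym[, 2L], value = x$values)
}

#' Convert a monthly series to a stats `ts` object (period 12)
#' @param x a `monthly_series`.
#' @return a `ts` with `frequency = 12`.
#' @export
as_ts <- function(x) {
  stats::ts(x$values, start = c(x$start[1L], x$start[2L]), frequency = 12)
}

#' Check that two series share the same month index
#' @param a,b `monthly_series` objects.
#' @return `TRUE`, invisibly; otherwise an alignment error is thrown.
#' @export
check_aligned <- function(a, b) {
  if (!identical(a$start, b$start) || length(a$values) != length(b$values)) {
    stop("series '", a$name, "' and '", b$name, "' are not aligned ",
         "(same start month and length required)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Split a monthly series into a training and a test part
#'
#' The second part starts at `first_test_month`; concatenating the two parts
#' recovers the input exactly. The boundary must lie strictly inside the
#' series span (both parts nonempty), matching the usual train/test protocol
#' where a model is fitted on an initial window and scored on the remainder.
#'
#' @param series a `monthly_series`.
#' @param first_test_month `c(year, month)` of the first test observation.
#' @return list with elements `train` and `test`, both `monthly_series`.
#' @examples
#' x <- monthly_series(1:24, c(2012, 1), "SM10", "kg/m3")
#' parts <- split_by_date(x, c(2013, 1))
#' length(parts$train)  # 12
#' @export
split_by_date <- function(series, first_test_month) {
  i0 <- .ym_index(series$start[1L], series$start[2L])
  ib <- .ym_index(first_test_month[1L], first_test_month[2L])
  n <- length(series$values)
  pos <- ib - i0  # 0-based offset of the boundary
  if (pos < 1L || pos > n - 1L) {
    stop("split month ", .ym_label(first_test_month[1L], first_test_month[2L]),
         " is not strictly inside the series span", call. = FALSE)
  }
  train <- monthly_series(series$values[seq_len(pos)], series$start,
                          series$name, series$unit, allow_na = TRUE)
  test <- monthly_series(series$values[(pos + 1L):n],
                         .index_ym(ib), series$name, series$unit,
                         allow_na = TRUE)
  list(train = train, test = test)
}

#' Aligned driver series for one site
#'
#' Bundles the five driver variables the water-balance model consumes:
#' precipitation `P`, soil evaporation `SE`, `NDVI`, `LAI` and the vegetation
#' coverage rate `VCR`. All present series must share the same month index.
#' `VCR` is the only series allowed to contain `NA` cells (it is typically
#' observed only on a short recent window and filled via [fill_vcr()]).
#'
#' @param p,se precipitation and soil evaporation, `mm/month`.
#' @param ndvi NDVI, dimensionless.
#' @param lai leaf area index, `m2/m2`.
#' @param vcr vegetation coverage rate in `[0, 1]`, `fraction`; may be `NULL`
#'   or contain `NA`.
#' @return an object of class `driver_set`.
#' @export
driver_set <- function(p, se, ndvi, lai, vcr = NULL) {
  for (s in list(se, ndvi, lai)) check_aligned(p, s)
  if (is.null(vcr)) {
    vcr <- monthly_series(rep(NA_real_, length(p$values)), p$start,
                          "VCR", "fraction", allow_na = TRUE)
  }
  check_aligned(p, vcr)
  obs <- vcr$values[!is.na(vcr$values)]
  if (length(obs) && (any(obs < 0) || any(obs > 1))) {
    stop("VCR values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(p = p, se = se, ndvi = ndvi, lai = lai, vcr = vcr),
            class = "driver_set")
}

#' @export
print.driver_set <- function(x, ...) {
  cat(sprintf("<driver_set> %d months from %s (VCR observed: %d)\n",
              length(x$p$values),
              .ym_label(x$p$start[1L], x$p$start[2L]),
              sum(!is.na(x$vcr$values))))
  invisible(x)
}

#' Multi-depth soil-moisture profile
#'
#' @param series named list of `monthly_series` (unit `kg/m3`), names are
#'   depths in cm; all series aligned; depths strictly increasing.
#' @return an object of class `sm_profile` with fields `depths` (integer
#'   vector, cm) and `series`.
#' @export
sm_profile <- function(series) {
  depths <- as.integer(names(series))
  if (anyNA(depths) || any(depths <= 0L) || any(diff(depths) <= 0L)) {
    stop("profile depths must be strictly increasing positive integers (cm)",
         call. = FALSE)
  }
  for (s in series[-1L]) check_aligned(series[[1L]], s)
  structure(list(depths = depths, series = series), class = "sm_profile")
}

#' @export
print.sm_profile <- function(x, ...) {
  cat(sprintf("<sm_profile> depths (cm): %s; %d months\n",
              paste(x$depths, collapse = ", "),
              length(x$series[[1L]]$values)))
  invisible(x)
}
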