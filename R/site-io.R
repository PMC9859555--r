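#' Read a site record from a wide monthly CSV
#'
#' The canonical exchange format is a wide CSV with one row per calendar
#' month and columns `year,month,P,SE,NDVI,LAI,VCR,SM10,SM40,...` (`SM<d>`
#' for soil moisture at depth d cm). `VCR` is optional and is the only column
#' whose cells may be empty; an empty cell anywhere else is an error, and a
#' gap in the month sequence is reported naming the first missing month.
#'
#' @param path path to the CSV file.
#' @return list with components `drivers` (a [driver_set()]) and
#'   `profile` (an [sm_profile()]).
#' @seealso [write_site_csv()]
#' @export
read_site_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("year", "month", "P", "SE", "NDVI", "LAI")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("malformed site CSV: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sm_cols <- grep("^SM[0-9]+$", names(df), value = TRUE)
  if (!length(sm_cols)) {
    stop("malformed site CSV: no SM<depth> soil-moisture columns", call. = FALSE)
  }
  if (nrow(df) < 1L) stop("malformed site CSV: no data rows", call. = FALSE)

  idx <- .ym_index(df$year, df$month)
  if (nrow(df) > 1L) {
    step <- diff(idx)
    if (any(step != 1L)) {
      first_gap <- .index_ym(idx[which(step != 1L)[1L]] + 1L)
      stop("malformed site CSV: month sequence has a gap; first missing month is ",
           .ym_label(first_gap[1L], first_gap[2L]), call. = FALSE)
    }
  }
  start <- c(df$year[1L], df$month[1L])

  strict_col <- function(col, unit) {
    v <- df[[col]]
    if (anyNA(v)) stop("column ", col, " has missing cells (only VCR may be absent)",
                       call. = FALSE)
    if (unit %in% c("mm/month", "kg/m3") && any(v < 0)) {
      stop("validation error: negative values in column ", col, call. = FALSE)
    }
    monthly_series(v, start, col, unit)
  }

  vcr <- monthly_series(if ("VCR" %in% names(df)) df$VCR else rep(NA_real_, nrow(df)),
                        start, "VCR", "fraction", allow_na = TRUE)
  drivers <- driver_set(
    p    = strict_col("P", "mm/month"),
    se   = strict_col("SE", "mm/month"),
    ndvi = strict_col("NDVI", "dimensionless"),
    lai  = strict_col("LAI", "m2/m2"),
    vcr  = vcr
  )
  depths <- sort(as.integer(sub("^SM", "", sm_cols)))
  series <- lapply(depths, function(d) strict_col(paste0("SM", d), "kg/m3"))
  names(series) <- depths
  list(drivers = drivers, profile = sm_profile(series))
}

#' Write a site record to the wide monthly CSV layout
#'
#' Inverse of [read_site_csv()]: a read/write/read round trip preserves the
#' month index, units and values exactly (up to CSV decimal printing, which
#' uses full double precision).
#'
#' @param drivers a [driver_set()].
#' @param profile an [sm_profile()] aligned with `drivers`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_csv <- function(drivers, profile, path) {
  check_aligned(drivers$p, profile$series[[1L]])
  ym <- series_months(drivers$p)
  df <- data.frame(year = ym[, 1L], month = ym[, 2L],
                   P = drivers$p$values, SE = drivers$se$values,
                   NDVI = drivers$ndvi$values, LAI = drivers$lai$values,
                   VCR = drivers$vcr$values)
  for (d in profile$depths) df[[paste0("SM", d)]] <- profile$series[[as.character(d)]]$values
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
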