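test_that("monthly series validate units, sign and month index", {
  x <- ms(1:12, c(2012, 1), "SM10", "kg/m3")
  expect_s3_class(x, "monthly_series")
  expect_equal(series_end(x), c(2012L, 12L))
  expect_equal(series_months(x)[5L, ], c(year = 2012L, month = 5L))

  expect_error(monthly_series(numeric(), c(2012, 1)), "at least one")
  expect_error(monthly_series(c(1, -2), c(2012, 1), "P", "mm/month"), "negative")
  expect_error(monthly_series(c(1, NA), c(2012, 1)), "missing")
  expect_error(monthly_series(1, c(2012, 13)), "month in 1..12")
  expect_error(monthly_series(1, c(2012, 1), unit = "furlongs"), "unknown unit")
  # NA allowed only when opted in (coverage-rate use case)
  expect_silent(monthly_series(c(0.1, NA), c(2012, 1), "VCR", "fraction",
                               allow_na = TRUE))
})

test_that("site CSV read/write/read is the identity on values, units and index", {
  site <- generate_site(site_scenario(years = 3, seed = 11))
  path <- write_temp_site(site)
  back <- read_site_csv(path)
  expect_equal(back$drivers$p$values, site$drivers$p$values)
  expect_equal(back$drivers$p$unit, "mm/month")
  expect_equal(back$drivers$lai$unit, "m2/m2")
  expect_identical(back$drivers$p$start, site$drivers$p$start)
  expect_identical(back$profile$depths, site$profile$depths)
  for (d in names(site$profile$series)) {
    expect_equal(back$profile$series[[d]]$values, site$profile$series[[d]]$values)
  }
  # and a second round trip through a fresh file
  path2 <- write_temp_site(back)
  again <- read_site_csv(path2)
  expect_equal(again$drivers$se$values, site$drivers$se$values)
})

test_that("reading rejects gaps (naming the first missing month) and bad cells", {
  df <- data.frame(year = c(2012, 2012), month = c(1, 3), P = c(1, 2),
                   SE = c(1, 1), NDVI = c(0.2, 0.2), LAI = c(0.5, 0.5),
                   VCR = c(NA, 0.1), SM10 = c(10, 11))
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, na = "")
  expect_error(read_site_csv(path), "2012-02")

  df$month <- c(1, 2)
  df$P <- c(-1, 2)
  write.csv(df, path, row.names = FALSE, na = "")
  expect_error(read_site_csv(path), "negative")

  df$P <- c(1, 2)
  df$SE <- c(1, NA)  # absent cells are only legal in VCR
  write.csv(df, path, row.names = FALSE, na = "")
  expect_error(read_site_csv(path), "only VCR")

  df$SE <- c(1, 1)
  write.csv(df, path, row.names = FALSE, na = "")
  got <- read_site_csv(path)
  expect_true(is.na(got$drivers$vcr$values[1L]))
  expect_error(read_site_csv(tempfile()), "not found")
})

test_that("a 123-row record spanning 2012-01..2022-03 loads and splits 108/15", {
  sc <- site_scenario(years = 11, seed = 5)
  site <- generate_site(sc)
  # truncate to the 123-month observation window
  cut <- function(s, unit) monthly_series(s$values[1:123], s$start, s$name, unit)
  p <- cut(site$drivers$p, "mm/month")
  expect_equal(series_end(p), c(2022L, 3L))
  parts <- split_by_date(p, c(2021, 1))
  expect_equal(length(parts$train), 108L)
  expect_equal(length(parts$test), 15L)
  expect_identical(parts$test$start, c(2021L, 1L))
})

test_that("split parts re-concatenate to the original at every interior boundary", {
  x <- ms(rnorm(30), c(2019, 7))
  idx <- series_months(x)
  for (i in c(2L, 3L, 15L, 29L, 30L)) {
    parts <- split_by_date(x, idx[i, ])
    expect_equal(c(parts$train$values, parts$test$values), x$values)
    expect_equal(length(parts$train), i - 1L)
  }
  # minimal train window
  parts <- split_by_date(x, idx[2L, ])
  expect_equal(length(parts$train), 1L)
})

test_that("split rejects boundaries outside or on the edge of the span", {
  x <- ms(1:12, c(2012, 1))
  expect_error(split_by_date(x, c(2012, 1)), "not strictly inside")
  expect_error(split_by_date(x, c(2013, 1)), "not strictly inside")
  expect_error(split_by_date(x, c(2030, 5)), "not strictly inside")
  one <- ms(1, c(2012, 1))
  expect_error(split_by_date(one, c(2012, 1)), "not strictly inside")
})

test_that("driver sets and profiles enforce alignment and ranges", {
  p <- ms(1:12, c(2012, 1), "P", "mm/month")
  se <- ms(1:12, c(2012, 1), "SE", "mm/month")
  nd <- ms(rep(0.2, 12), c(2012, 1), "NDVI")
  lai <- ms(rep(0.5, 12), c(2012, 1), "LAI", "m2/m2")
  short <- ms(1:11, c(2012, 1), "SE", "mm/month")
  expect_error(driver_set(p, short, nd, lai), "not aligned")
  bad_vcr <- monthly_series(rep(1.5, 12), c(2012, 1), "VCR", "fraction")
  expect_error(driver_set(p, se, nd, lai, bad_vcr), "\\[0, 1\\]")
  ok <- driver_set(p, se, nd, lai)
  expect_true(all(is.na(ok$vcr$values)))

  sm <- list("40" = ms(1:12, c(2012, 1), "SM40", "kg/m3"),
             "10" = ms(1:12, c(2012, 1), "SM10", "kg/m3"))
  expect_error(sm_profile(sm), "strictly increasing")
})
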