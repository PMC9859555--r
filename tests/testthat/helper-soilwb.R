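# shared helpers for the soilwb test suite

# quick series constructor
ms <- function(values, start = c(2012, 1), name = "x", unit = "dimensionless") {
  monthly_series(values, start, name, unit)
}

# printed tables carry 4 decimals; recomputing from rounded inputs can move
# a value by up to one unit in the last printed digit
printed_tol <- 1.5e-4

# write a site CSV for a generated record and return the path
write_temp_site <- function(site) {
  path <- tempfile(fileext = ".csv")
  write_site_csv(site$drivers, site$profile, path)
  path
}
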