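# Fixture builders shared across the suite. Everything is generated in code;
# seeds are fixed per test for reproducibility.

mt <- marindown::monthly_times

# Uniform small grid with all-ocean mask.
toy_grid <- function(nlat = 4, nlon = 4, lat0 = 54, lon0 = 2, res = 0.5) {
  md_grid(lat0 + (seq_len(nlat) - 0.5) * res, lon0 + (seq_len(nlon) - 0.5) * res)
}

# Field with values given by f(time_index, lat, lon).
toy_field <- function(grid, times, f = function(t, la, lo) 0 * la,
                      variable = "temperature", units = "degC") {
  nt <- length(times)
  v <- array(NA_real_, c(nt, length(grid$lats), length(grid$lons)))
  for (t in seq_len(nt)) for (i in seq_along(grid$lats)) for (j in seq_along(grid$lons))
    v[t, i, j] <- f(t, grid$lats[i], grid$lons[j])
  gridded_field(grid, v, times, variable, units)
}

# Constant-in-space field from a time series of values.
series_field <- function(grid, times, values_by_time, ...) {
  toy_field(grid, times, function(t, la, lo) values_by_time[t], ...)
}

# Independent haversine used by IDW oracles (6371 km sphere).
oracle_haversine <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dphi <- (lat2 - lat1) * rad
  dlam <- (lon2 - lon1) * rad
  a <- sin(dphi / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlam / 2)^2
  2 * 6371000 * asin(pmin(1, sqrt(a)))
}

# Small AR(1) series for DQM tests.
toy_series <- function(years = c(1993, 2014), mean = 10, trend_yr = 0.02,
                       sd = 1, seed = 1) {
  times <- mt(years[1], years[2])
  set.seed(seed)
  n <- length(times)
  vals <- mean + trend_yr * (seq_len(n) - (n + 1) / 2) / 12 + rnorm(n, sd = sd)
  md_series(times, vals)
}
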