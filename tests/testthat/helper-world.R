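# Shared synthetic world used across test files: a small coastal domain
# with a meridian shoreline, a 2-year warm extreme at the end of the
# record, and a 5-member monthly-initialized forecast ensemble.

tw_grid <- make_grid(c(34, 41), c(-122, -116), resolution = 1)
tw_band75 <- coastal_band(tw_grid, 75, 35, 40)
tw_band150 <- coastal_band(tw_grid, 150, 35, 40)
tw_box <- region_box(tw_grid, 34, 37, -121, -117)
tw_clim_years <- 1981:2010

tw_obs <- simulate_observed_sst(
  tw_grid, years = 1981:2012,
  heatwaves = heatwave(c(2011, 1), c(2012, 12), amplitude = 2),
  seed = 101
)

tw_fc <- simulate_forecasts(
  tw_obs, tw_grid, skill_profile(rho0 = 0.95, decay = 0.99),
  n_members = 5, seed = 102
)

# A noise-free world: pure latitude + seasonal climatology, identical
# every year. Useful wherever exact arithmetic is asserted.
tw_obs_quiet <- simulate_observed_sst(
  tw_grid, years = 2001:2010,
  ar1 = 0, anomaly_sd = 0, cell_noise_sd = 0, seed = 7
)

# Hand-built toy SST fixture: 2 cells, 2 years, values chosen so monthly
# means are easy to compute independently.
toy_sst <- function() {
  g <- tidyr::expand_grid(year = 2001:2002, month = 1:12, cell = c(1L, 2L))
  g$sst <- g$month + 0.5 * (g$year - 2001) + 2 * (g$cell - 1)
  g$date <- as.Date(sprintf("%d-%02d-01", g$year, g$month))
  g[, c("date", "year", "month", "cell", "sst")]
}

# Independent haversine (law-of-haversines written out), used as the
# distance oracle against the geosphere-backed implementation.
oracle_haversine_km <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}
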