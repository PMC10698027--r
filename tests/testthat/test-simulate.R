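test_that("a noise-free simulation is pure climatology, identical every year", {
  by_cm <- tw_obs_quiet |>
    dplyr::group_by(cell, month) |>
    dplyr::summarise(n_unique = dplyr::n_distinct(sst), .groups = "drop")
  expect_true(all(by_cm$n_unique == 1))
})

test_that("a heatwave adds its amplitude to the anomaly inside the window", {
  hw <- heatwave(c(2005, 1), c(2006, 12), amplitude = 2)
  obs <- simulate_observed_sst(tw_grid, years = 2001:2010, ar1 = 0,
                               anomaly_sd = 0, cell_noise_sd = 0,
                               heatwaves = hw, seed = 3)
  clim <- obs |>
    dplyr::filter(!(year %in% 2005:2006)) |>
    dplyr::group_by(cell, month) |>
    dplyr::summarise(clim = mean(sst), .groups = "drop")
  anom <- obs |>
    dplyr::inner_join(clim, by = c("cell", "month")) |>
    dplyr::mutate(anom = sst - clim)
  expect_equal(mean(anom$anom[anom$year %in% 2005:2006]), 2, tolerance = 1e-12)
  expect_equal(mean(anom$anom[!(anom$year %in% 2005:2006)]), 0,
               tolerance = 1e-12)
})

test_that("the AR(1) coefficient of domain-mean anomalies is recoverable", {
  obs <- simulate_observed_sst(tw_grid, years = 1981:2020, ar1 = 0.6,
                               anomaly_sd = 0.8, cell_noise_sd = 0, seed = 11)
  dm <- obs |>
    dplyr::group_by(date, month) |>
    dplyr::summarise(sst = mean(sst), .groups = "drop") |>
    dplyr::group_by(month) |>
    dplyr::mutate(anom = sst - mean(sst)) |>
    dplyr::ungroup() |>
    dplyr::arrange(date)
  r1 <- acf(dm$anom, lag.max = 1, plot = FALSE)$acf[2]
  expect_equal(r1, 0.6, tolerance = 0.08)
})

test_that("fixed seeds reproduce observed fields and forecasts bit for bit", {
  o1 <- simulate_observed_sst(tw_grid, years = 2001:2005, seed = 5)
  o2 <- simulate_observed_sst(tw_grid, years = 2001:2005, seed = 5)
  expect_identical(o1, o2)
  f1 <- simulate_forecasts(o1, tw_grid, skill_profile(0.9, 0.95),
                           n_members = 2, seed = 6)
  f2 <- simulate_forecasts(o2, tw_grid, skill_profile(0.9, 0.95),
                           n_members = 2, seed = 6)
  expect_identical(f1, f2)
})

test_that("heatwave windows outside the simulated years are rejected", {
  expect_error(
    simulate_observed_sst(tw_grid, years = 2001:2005,
                          heatwaves = heatwave(c(2006, 1), c(2006, 6), 1)),
    "outside the simulated years"
  )
  expect_error(heatwave(c(2005, 6), c(2005, 1), 1), "start")
  expect_error(heatwave(c(2005, 1), c(2005, 6), -1), "amplitude")
})

test_that("a perfect profile reproduces the observations at every lead", {
  prof <- skill_profile(rho0 = 1, decay = 1, drift_bias = 0)
  fc <- simulate_forecasts(tw_obs_quiet, tw_grid, prof, n_members = 2,
                           init_years = 2001:2009, seed = 8)
  joined <- dplyr::inner_join(
    fc, tw_obs_quiet[, c("year", "month", "cell", "sst")],
    by = c("target_year" = "year", "target_month" = "month", "cell" = "cell"),
    suffix = c("_fc", "_obs")
  )
  expect_equal(joined$sst_fc, joined$sst_obs, tolerance = 1e-12)
})

test_that("drift bias accumulates linearly with lead", {
  prof <- skill_profile(rho0 = 1, decay = 1, drift_bias = 0.1)
  fc <- simulate_forecasts(tw_obs_quiet, tw_grid, prof, n_members = 1,
                           init_years = 2001:2009, seed = 9)
  joined <- dplyr::inner_join(
    fc, tw_obs_quiet[, c("year", "month", "cell", "sst")],
    by = c("target_year" = "year", "target_month" = "month", "cell" = "cell"),
    suffix = c("_fc", "_obs")
  )
  err <- joined |>
    dplyr::group_by(lead) |>
    dplyr::summarise(bias = mean(sst_fc - sst_obs), .groups = "drop")
  expect_equal(err$bias, 0.1 * err$lead, tolerance = 1e-10)
  expect_equal(err$bias[err$lead == 11.5], 1.15, tolerance = 1e-10)
})

test_that("the lead-dependent correlation profile is recoverable", {
  obs <- simulate_observed_sst(tw_grid, years = 1981:2015, ar1 = 0.3,
                               anomaly_sd = 0.8, cell_noise_sd = 0.1,
                               seed = 21)
  prof <- skill_profile(rho0 = 0.9, decay = 0.95)
  fc <- simulate_forecasts(obs, tw_grid, prof, n_members = 1, seed = 22)
  obs_dm <- obs |>
    dplyr::group_by(year, month) |>
    dplyr::summarise(obs_sst = mean(sst), .groups = "drop") |>
    dplyr::group_by(month) |>
    dplyr::mutate(obs_anom = obs_sst - mean(obs_sst)) |>
    dplyr::ungroup()
  fc_dm <- fc |>
    dplyr::group_by(lead, target_year, target_month) |>
    dplyr::summarise(fc_sst = mean(sst), .groups = "drop") |>
    dplyr::group_by(lead, target_month) |>
    dplyr::mutate(fc_anom = fc_sst - mean(fc_sst)) |>
    dplyr::ungroup()
  rho_hat <- fc_dm |>
    dplyr::inner_join(obs_dm, by = c("target_year" = "year",
                                     "target_month" = "month")) |>
    dplyr::group_by(lead) |>
    dplyr::summarise(r = cor(fc_anom, obs_anom), n = dplyr::n(),
                     .groups = "drop")
  expect_true(all(rho_hat$n >= 300))
  expect_equal(rho_hat$r, rho_at_lead(prof, rho_hat$lead), tolerance = 0.08)
})

test_that("ensemble-mean anomaly error variance shrinks with member count", {
  prof <- skill_profile(rho0 = 0.7, decay = 1)
  fc <- simulate_forecasts(tw_obs, tw_grid, prof, n_members = 20,
                           init_months = c(1, 7), seed = 31)
  obs_dm <- tw_obs |>
    dplyr::group_by(year, month) |>
    dplyr::summarise(obs_sst = mean(sst), .groups = "drop")
  per_member <- fc |>
    dplyr::group_by(member, lead, target_year, target_month) |>
    dplyr::summarise(fc_sst = mean(sst), .groups = "drop") |>
    dplyr::inner_join(obs_dm, by = c("target_year" = "year",
                                     "target_month" = "month"))
  members <- sort(unique(per_member$member))
  err_var <- function(k) {
    per_member |>
      dplyr::filter(member %in% members[seq_len(k)]) |>
      dplyr::group_by(lead, target_year, target_month, obs_sst) |>
      dplyr::summarise(fc = mean(fc_sst), .groups = "drop") |>
      dplyr::summarise(v = stats::var(fc - obs_sst)) |>
      dplyr::pull(v)
  }
  v <- vapply(c(1, 5, 20), err_var, numeric(1))
  expect_true(v[2] < v[1])
  expect_true(v[3] < v[2])
})

test_that("leads beyond the observed coverage are rejected", {
  expect_error(
    simulate_forecasts(tw_obs_quiet, tw_grid, skill_profile(0.9, 0.95),
                       n_members = 1, init_years = 2010, seed = 1),
    "coverage"
  )
})

test_that("target months follow the mid-month lead convention", {
  jan <- as.Date("2005-01-01")
  expect_equal(lead_target(jan, 0.5), as.Date("2005-01-01"))
  expect_equal(lead_target(jan, 11.5), as.Date("2005-12-01"))
  expect_equal(lead_target(as.Date("2005-07-01"), 5.5), as.Date("2005-12-01"))
  sub <- dplyr::slice_sample(tw_fc, n = 500)
  expect_equal(sub$target, lead_target(sub$init, sub$lead))
})
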