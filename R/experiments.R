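# Replicated synthetic experiments: the ensemble-size ordering study and
# the heatwave forewarning study. Both are driven by the same machinery
# the pipeline uses; they exist as functions so tests and the acceptance
# script run the identical experiment.

#' Ensemble-size ordering experiment
#'
#' Replicates small synthetic worlds and verifies, per world, the HCI
#' correlation skill of three forecast configurations sharing the
#' twice-yearly (January/July) schedule: the full global ensemble, a
#' 3-member subset of it (the 2nd, 8th and 10th members), and a separate
#' "downscaled" ensemble whose members are individually more skilful.
#' With members of equal individual skill the large ensemble should beat
#' its own 3-member subset almost everywhere (averaging suppresses member
#' noise); when the 3 downscaled members are given sufficiently higher
#' target correlation they overtake the full ensemble, reversing the
#' ordering.
#'
#' @param n_worlds Number of replicate worlds.
#' @param seed Base seed; world w uses `seed + 1000 * w` offsets.
#' @param years,clim_years Simulated span and climatology years.
#' @param global_profile,downscaled_profile [skill_profile()]s for the
#'   global members and the downscaled members.
#' @param n_global,n_downscaled Ensemble sizes (73 vs 3 in the emulated
#'   study design).
#' @return A tibble with one row per (world, ensemble, target month,
#'   lead): the correlation `r` between ensemble-mean and observed HCI.
#' @export
experiment_ensemble_ordering <- function(n_worlds = 20, seed = 1,
                                         years = 1981:2011,
                                         clim_years = 1981:2010,
                                         global_profile = skill_profile(0.5, 0.9),
                                         downscaled_profile = skill_profile(0.995, 0.995),
                                         n_global = 73, n_downscaled = 3) {
  grid <- make_grid(c(34, 41), c(-119, -116), resolution = 1)
  band75 <- coastal_band(grid, 75, 35, 40)
  band150 <- coastal_band(grid, 150, 35, 40)
  init_years <- years[seq_len(length(years) - 1)]

  purrr::map_dfr(seq_len(n_worlds), function(w) {
    s <- as.integer(seed) + 1000L * w
    obs <- simulate_observed_sst(grid, years, seed = s)
    thr <- monthly_thresholds(obs, band75, clim_years)
    obs_h <- hci_series(obs, thr, band150)
    g_fc <- simulate_forecasts(obs, grid, global_profile, n_global,
                               init_months = c(1, 7),
                               init_years = init_years,
                               cells = band150$cell, seed = s + 1L)
    members <- sort(unique(g_fc$member))
    d_fc <- simulate_forecasts(obs, grid, downscaled_profile, n_downscaled,
                               init_months = c(1, 7),
                               init_years = init_years,
                               cells = band150$cell, model = "downscaled",
                               seed = s + 2L)
    sets <- list(
      full = g_fc,
      reduced = dplyr::filter(g_fc, member %in% members[c(2, 8, 10)]),
      downscaled = d_fc
    )
    purrr::imap_dfr(sets, function(fc, nm) {
      ens <- forecast_hci(fc, band75, band150, clim_years)
      dplyr::inner_join(
        dplyr::select(obs_h, year, month, obs_hci = hci),
        dplyr::select(ens, target_year, target_month, lead, hci),
        by = c("year" = "target_year", "month" = "target_month")
      ) |>
        dplyr::group_by(target_month = month, lead) |>
        dplyr::summarise(r = cor(hci, obs_hci), n = dplyr::n(),
                         .groups = "drop") |>
        dplyr::mutate(ensemble = nm, world = w)
    })
  })
}

#' Fraction of month-by-lead cells where one ensemble out-correlates another
#'
#' @param ordering Output of [experiment_ensemble_ordering()].
#' @param winner,loser Ensemble labels to compare.
#' @return The pooled fraction of (world, month, lead) cells where
#'   `winner`'s correlation exceeds `loser`'s.
#' @export
ordering_win_fraction <- function(ordering, winner, loser) {
  wide <- ordering |>
    tidyr::pivot_wider(id_cols = c(world, target_month, lead),
                       names_from = ensemble, values_from = r)
  mean(wide[[winner]] > wide[[loser]])
}

#' Heatwave forewarning experiment
#'
#' Builds a world with a multi-year domain-wide warm extreme late in the
#' record (and a control world identical except for the heatwave) and
#' asks the two management tools the operational questions: at short
#' lead, how often are in-heatwave months forecast as high-compression?
#' And is at least one June-August closure recommended half a year or
#' more ahead? The control world is scored with the same decision rules
#' (the closure rule transfers the heatwave world's absolute threshold,
#' since a world without closures defines none of its own).
#'
#' @param seed Base seed.
#' @param years Simulated span; the heatwave occupies the final
#'   `heatwave_years`.
#' @param clim_years Climatology years (must precede the heatwave).
#' @param heatwave_years Calendar years of the warm extreme.
#' @param amplitude Heatwave amplitude in degrees C.
#' @param profile Forecast skill profile (keep the implied correlation
#'   high at all leads for a forewarning test).
#' @param n_members Ensemble size.
#' @return A list of summary statistics for the heatwave and control
#'   worlds: the lead-0.5 HCI event rate inside the heatwave window, the
#'   control's long-run (full-record) and window event rates, closure
#'   counts at leads >= 6.5, the earliest closure lead, and the closure
#'   threshold with its percentile.
#' @export
experiment_heatwave_forewarning <- function(seed = 1, years = 1981:2012,
                                            clim_years = 1981:2010,
                                            heatwave_years = 2011:2012,
                                            amplitude = 2,
                                            profile = skill_profile(0.95, 0.99),
                                            n_members = 5) {
  grid <- make_grid(c(34, 41), c(-119, -116), resolution = 1)
  band75 <- coastal_band(grid, 75, 35, 40)
  band150 <- coastal_band(grid, 150, 35, 40)
  box <- region_box(grid, 34, 37, -118, -116)
  cells <- union(band150$cell, box$cell)
  hw <- heatwave(c(min(heatwave_years), 1), c(max(heatwave_years), 12),
                 amplitude = amplitude)
  in_window <- function(y) y %in% heatwave_years
  seed <- as.integer(seed)

  run_world <- function(heatwaves, world_seed) {
    obs <- simulate_observed_sst(grid, years, heatwaves = heatwaves,
                                 seed = world_seed)
    fc <- simulate_forecasts(obs, grid, profile, n_members,
                             cells = cells, seed = world_seed + 1L)
    thr <- monthly_thresholds(obs, band75, clim_years)
    obs_h <- hci_series(obs, thr, band150) |>
      classify_high_compression(clim_years = clim_years)
    fc_h <- forecast_hci(fc, band75, band150, clim_years)
    ssta <- box_mean_ssta(obs, box, clim_years)
    rt <- rolling_total(ssta)
    obs_total <- total_series(ssta)
    fc_total <- forecast_total(fc, box, clim_years)
    list(obs = obs, obs_hci = obs_h, fc_hci = fc_h, obs_total = obs_total,
         rolling = rt, fc_total = fc_total)
  }

  hw_world <- run_world(list(hw), seed)
  ctl_world <- run_world(list(), seed + 100L)

  closures <- dplyr::bind_rows(
    tibble::tibble(year = heatwave_years[1], month = 8L),
    tidyr::expand_grid(year = heatwave_years[-1], month = 6:8)
  )
  thr_obs <- closure_threshold(hw_world$obs_total, closures,
                               distribution = hw_world$rolling$total)
  thr_lead <- forecast_closure_thresholds(hw_world$fc_total,
                                          thr_obs$percentile)

  hw_closures <- hw_world$fc_total |>
    dplyr::left_join(thr_lead, by = "lead") |>
    dplyr::mutate(closure = recommend_closure(total, threshold)) |>
    dplyr::filter(lead >= 6.5, in_window(target_year))
  ctl_closures <- ctl_world$fc_total |>
    dplyr::mutate(closure = recommend_closure(total, thr_obs$value)) |>
    dplyr::filter(lead >= 6.5, in_window(target_year))

  hci_rate <- function(world, window_only) {
    sub <- dplyr::filter(world$fc_hci, lead == 0.5)
    if (window_only) sub <- dplyr::filter(sub, in_window(target_year))
    mean(sub$event)
  }

  list(
    hci_rate_heatwave = hci_rate(hw_world, window_only = TRUE),
    # the control's triggering rate is its long-run event frequency; a
    # single 2-year window of a persistent AR(1) anomaly field is not an
    # estimator of it (one warm excursion can fill the whole window)
    hci_rate_control = hci_rate(ctl_world, window_only = FALSE),
    hci_rate_control_window = hci_rate(ctl_world, window_only = TRUE),
    obs_hci_rate_heatwave = mean(
      hw_world$obs_hci$event[in_window(hw_world$obs_hci$year)]
    ),
    closure_threshold = thr_obs$value,
    closure_percentile = thr_obs$percentile,
    n_window_closure_forecasts = nrow(hw_closures),
    closures_heatwave = sum(hw_closures$closure),
    earliest_closure_lead = if (any(hw_closures$closure)) {
      max(hw_closures$lead[hw_closures$closure])
    } else {
      NA_real_
    },
    closures_control = sum(ctl_closures$closure)
  )
}
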