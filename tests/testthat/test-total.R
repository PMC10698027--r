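test_that("SSTA is zero when SST equals its climatology and shifts with offsets", {
  ssta <- box_mean_ssta(tw_obs_quiet, tw_box, 2001:2010)
  expect_equal(ssta$ssta, rep(0, nrow(ssta)), tolerance = 1e-12)
  shifted <- tw_obs_quiet
  shifted$sst <- shifted$sst + 1
  ssta1 <- box_mean_ssta(shifted, tw_box, 2001:2010)
  # climatology recomputed on the shifted data -> still zero; against the
  # original climatology the anomaly is exactly +1
  clim_ref <- tw_obs_quiet |>
    dplyr::filter(cell %in% tw_box$cell) |>
    dplyr::group_by(cell, month) |>
    dplyr::summarise(clim = mean(sst), .groups = "drop")
  anom1 <- shifted |>
    dplyr::filter(cell %in% tw_box$cell) |>
    dplyr::inner_join(clim_ref, by = c("cell", "month")) |>
    dplyr::group_by(date) |>
    dplyr::summarise(ssta = mean(sst - clim), .groups = "drop")
  expect_equal(anom1$ssta, rep(1, nrow(anom1)), tolerance = 1e-12)
  expect_equal(ssta1$ssta, rep(0, nrow(ssta1)), tolerance = 1e-12)
})

test_that("box-mean SSTA equals hand-computed means on a 2-cell fixture", {
  sst <- toy_sst()
  box <- tw_box[1:2, ]
  box$cell <- c(1L, 2L)
  ssta <- box_mean_ssta(sst, box, 2001:2002)
  # climatology per cell is month + 0.25 (+2 for cell 2); the box-mean
  # anomaly is -0.25 in 2001 and +0.25 in 2002, every month
  expect_equal(ssta$ssta, rep(c(-0.25, 0.25), each = 12), tolerance = 1e-12)
})

test_that("TOTAL is the mean of the six strictly preceding months", {
  ssta <- tibble::tibble(
    year = rep(2001, 12), month = 1:12,
    date = as.Date(sprintf("2001-%02d-01", 1:12)),
    ssta = c(0, 0, 0, 0, 0, 6, rep(1, 6))
  )
  # a December-May window of 0,0,0,0,0,6 would give 1; here Jan-Jun
  # precede July, so the July value is mean(0,0,0,0,0,6) = 1
  tot <- total_series(ssta, closure_months = 7)
  expect_equal(tot$total, 1)
  # constant series: TOTAL equals the constant
  const <- dplyr::mutate(ssta, ssta = 0.7)
  tot_c <- rolling_total(const)
  expect_equal(tot_c$total[7:12], rep(0.7, 6))
  expect_true(all(is.na(tot_c$total[1:6])))  # incomplete windows flagged
})

test_that("TOTAL matches a brute-force sliding-window oracle", {
  withr::with_seed(13, {
    x <- rnorm(24)
  })
  ssta <- tibble::tibble(
    year = rep(2001:2002, each = 12), month = rep(1:12, 2),
    date = as.Date(sprintf("%d-%02d-01", rep(2001:2002, each = 12),
                           rep(1:12, 2))),
    ssta = x
  )
  rt <- rolling_total(ssta)
  oracle <- vapply(seq_along(x), function(i) {
    if (i < 7) return(NA_real_)
    mean(x[(i - 6):(i - 1)])
  }, numeric(1))
  expect_equal(rt$total, oracle)
  # and via zoo as an independent library oracle
  zoo_oracle <- c(rep(NA, 6), zoo::rollmean(x, 6)[1:(length(x) - 6)])
  expect_equal(rt$total, zoo_oracle)
})

test_that("the closure threshold is the minimum TOTAL across historical closures", {
  totals <- tibble::tibble(
    year = c(2014, 2015, 2015, 2015), month = c(8, 6, 7, 8),
    total = c(0.5, 0.7, 0.9, 0.6)
  )
  thr <- closure_threshold(totals, list(c(2014, 8), c(2015, 6), c(2015, 7)),
                           distribution = c(-1, -0.5, 0, 0.2, 0.5, 0.7, 0.9))
  expect_equal(thr$value, 0.5)
  # mid-rank: 4 values strictly below, 1 tie counted half, of 7
  expect_equal(thr$percentile, 100 * 4.5 / 7)
  expect_error(
    closure_threshold(totals, list(c(2016, 6)),
                      distribution = totals$total),
    "undefined"
  )
  # all closure values equal: percentile < 100 whenever colder values exist
  eq <- dplyr::mutate(totals, total = 0.5)
  thr_eq <- closure_threshold(eq, list(c(2014, 8), c(2015, 6)),
                              distribution = c(-0.2, 0.1, 0.5, 0.5))
  expect_equal(thr_eq$value, 0.5)
  expect_lt(thr_eq$percentile, 100)
})

test_that("closure recommendation uses the at-or-above rule", {
  expect_true(recommend_closure(0.41, 0.41))
  expect_false(recommend_closure(0.41 - 1e-9, 0.41))
  expect_false(recommend_closure(0.41, 0.41, comparator = "gt"))
})

test_that("TOTAL and its threshold are translation-equivariant", {
  ssta <- box_mean_ssta(tw_obs, tw_box, tw_clim_years)
  rt <- rolling_total(ssta)
  tot <- total_series(ssta)
  closures <- list(c(2011, 8), c(2012, 6), c(2012, 7), c(2012, 8))
  thr <- closure_threshold(tot, closures, distribution = rt$total)

  shifted <- dplyr::mutate(ssta, ssta = ssta + 0.37)
  rt_s <- rolling_total(shifted)
  tot_s <- total_series(shifted)
  thr_s <- closure_threshold(tot_s, closures, distribution = rt_s$total)

  expect_equal(tot_s$total, tot$total + 0.37, tolerance = 1e-12)
  expect_equal(thr_s$value, thr$value + 0.37, tolerance = 1e-12)
  expect_equal(thr_s$percentile, thr$percentile)
  expect_equal(recommend_closure(tot_s$total, thr_s),
               recommend_closure(tot$total, thr))
})

test_that("closure frequency matches the threshold percentile on stationary data", {
  obs <- simulate_observed_sst(tw_grid, years = 1981:2020, seed = 77)
  rt <- rolling_total(box_mean_ssta(obs, tw_box, 1981:2020))
  vals <- rt$total[!is.na(rt$total)]
  thr <- quantile(vals, 0.74, type = 7, names = FALSE)
  # by construction ~26% of eligible months exceed the 74th percentile
  expect_equal(mean(vals >= thr), 0.26, tolerance = 0.02)
  f_closure <- mean(rt$total[rt$month %in% 6:8] >= thr, na.rm = TRUE)
  expect_equal(f_closure, 0.26, tolerance = 0.15)
})

test_that("forecast TOTAL windows match per-init brute force", {
  ft_member <- forecast_total(tw_fc, tw_box, tw_clim_years, by_member = TRUE)
  expect_true(all(ft_member$lead >= 6.5))
  ssta <- forecast_box_ssta(tw_fc, tw_box, tw_clim_years)
  pick <- ft_member[c(1, 25, 100), ]
  for (i in seq_len(nrow(pick))) {
    w <- ssta[ssta$member == pick$member[i] & ssta$init == pick$init[i] &
                ssta$lead >= pick$lead[i] - 6 & ssta$lead <= pick$lead[i] - 1, ]
    expect_equal(pick$total[i], mean(w$ssta), tolerance = 1e-12)
  }
  # ensemble means average the members
  ft <- forecast_total(tw_fc, tw_box, tw_clim_years)
  one <- ft[ft$lead == 8.5 & ft$target == as.Date("2000-07-01"), ]
  mem <- ft_member[ft_member$lead == 8.5 &
                     ft_member$target == as.Date("2000-07-01"), ]
  expect_equal(one$total, mean(mem$total))
})

test_that("twice-yearly TOTAL composition follows the coverage table", {
  cov <- total_coverage_table()
  expect_equal(nrow(cov), 18)
  expect_equal(sort(unique(cov$closure_month)), 6:8)
  expect_true(all(dplyr::count(cov, closure_month)$n == 6))

  dfc <- simulate_forecasts(tw_obs, tw_grid, skill_profile(0.98, 0.995),
                            n_members = 2, init_months = c(1, 7),
                            model = "downscaled", seed = 44)
  dt_member <- forecast_total_composite(dfc, tw_box, tw_clim_years,
                                        by_member = TRUE)
  ssta <- forecast_box_ssta(dfc, tw_box, tw_clim_years)
  # June of year y: Dec from the Jul (y-1) run at lead 5.5 plus Jan-May
  # from the Jan (y) run at leads 0.5-4.5
  row <- dt_member[dt_member$target_year == 2000 & dt_member$target_month == 6 &
                     dt_member$member == dt_member$member[1], ]
  jul_part <- ssta$ssta[ssta$member == row$member & ssta$lead == 5.5 &
                          ssta$init == as.Date("1999-07-01")]
  jan_part <- ssta$ssta[ssta$member == row$member & ssta$lead %in% seq(0.5, 4.5) &
                          ssta$init == as.Date("2000-01-01")]
  expect_equal(row$total, mean(c(jul_part, jan_part)), tolerance = 1e-12)
  expect_equal(row$lead_max, 5.5)
})

test_that("lead-specific forecast thresholds hit the requested quantile", {
  ft <- forecast_total(tw_fc, tw_box, tw_clim_years)
  thr <- forecast_closure_thresholds(ft, 74)
  expect_equal(sort(thr$lead), sort(unique(ft$lead)))
  one_lead <- ft$total[ft$lead == 7.5]
  expect_equal(thr$threshold[thr$lead == 7.5],
               quantile(one_lead, 0.74, type = 7, names = FALSE))
})
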