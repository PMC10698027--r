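# TOTAL indicator: the mean SST anomaly over the six months preceding a
# candidate closure month (June, July or August) in the Southern
# California Bight box. Anomalies above a threshold -- the minimum TOTAL
# value across historical loggerhead-bycatch closures -- recommend a
# fishery closure.

#' Box-mean SST anomaly series
#'
#' Subtracts each cell's monthly climatology (over `clim_years`) and
#' averages the anomalies over a box mask, giving one SSTA value per month.
#'
#' @param sst SST tibble with `date`, `year`, `month`, `cell`, `sst`.
#' @param box A [region_box()] mask.
#' @param clim_years Years defining the monthly climatology.
#' @return A tibble with `date`, `year`, `month`, `ssta` (degrees C).
#' @export
box_mean_ssta <- function(sst, box, clim_years) {
  stopifnot(nrow(box) > 0)
  sub <- sst[sst$cell %in% box$cell, ]
  if (nrow(sub) == 0) stop("no SST values inside the box", call. = FALSE)
  clim <- sub[sub$year %in% clim_years, ] |>
    dplyr::group_by(cell, month) |>
    dplyr::summarise(clim = mean(sst), .groups = "drop")
  if (dplyr::n_distinct(clim$month) < 12L) {
    stop("climatology years do not cover all 12 months", call. = FALSE)
  }
  sub |>
    dplyr::inner_join(clim, by = c("cell", "month")) |>
    dplyr::group_by(date, year, month) |>
    dplyr::summarise(ssta = mean(sst - clim), .groups = "drop") |>
    dplyr::arrange(date)
}

#' Six-month trailing mean of an SSTA series
#'
#' For every month t, the mean SSTA of the six months strictly preceding
#' t (for a June value: December through May). Months without a complete
#' six-month window are `NA`, flagged rather than dropped.
#'
#' @param ssta A [box_mean_ssta()] tibble (`date`, `year`, `month`, `ssta`).
#' @return The input with a `total` column.
#' @export
rolling_total <- function(ssta) {
  ssta <- dplyr::arrange(ssta, date)
  idx <- ym_index(ssta$year, ssta$month)
  if (nrow(ssta) > 1 && !all(diff(idx) == 1L)) {
    stop("SSTA series must cover consecutive months", call. = FALSE)
  }
  x <- ssta$ssta
  n <- length(x)
  tot <- rep(NA_real_, n)
  if (n >= 7) {
    cs <- cumsum(x)
    k <- 7:n
    tot[k] <- (cs[k - 1] - c(0, cs)[k - 6]) / 6
  }
  ssta$total <- tot
  ssta
}

#' TOTAL values at candidate closure months
#'
#' @inheritParams rolling_total
#' @param closure_months Calendar months eligible for a closure (default
#'   June-August).
#' @return A tibble with `date`, `year`, `month`, `total` at the closure
#'   months (NA when the preceding window is incomplete).
#' @examples
#' # June TOTAL is the Dec-May mean SSTA
#' @export
total_series <- function(ssta, closure_months = 6:8) {
  rt <- rolling_total(ssta)
  rt[rt$month %in% closure_months, c("date", "year", "month", "total")]
}

#' Closure threshold from historical closures
#'
#' The closure threshold is the minimum TOTAL value across the months when
#' closures were historically enacted (for the real tool: Aug 2014,
#' Jun-Aug 2015 and Jun-Aug 2016). The threshold is also expressed as a
#' percentile of the TOTAL-eligible SSTA distribution -- the 6-month
#' trailing means at every month with a complete window -- so it can be
#' transferred to forecast distributions lead by lead. The percentile is
#' the mid-rank of the threshold within the distribution (ties count
#' half), reported on 0-100.
#'
#' @param totals A [total_series()] (or [rolling_total()]) tibble.
#' @param closures Historical closures: a data frame with `year` and
#'   `month` columns, or a list of `c(year, month)` pairs.
#' @param distribution Numeric vector defining the reference distribution
#'   for the percentile; defaults to `totals$total` (complete windows only).
#' @return An object of class `closure_threshold`: `value` (degrees C),
#'   `percentile` (0-100, proportion of the distribution <= value),
#'   `closures`, `n` (distribution size).
#' @export
closure_threshold <- function(totals, closures, distribution = NULL) {
  closures <- normalize_closures(closures)
  key <- ym_index(totals$year, totals$month)
  want <- ym_index(closures$year, closures$month)
  pos <- match(want, key)
  if (anyNA(pos) || anyNA(totals$total[pos])) {
    stop("TOTAL undefined at one or more historical closure months",
         call. = FALSE)
  }
  vals <- totals$total[pos]
  value <- min(vals)
  dist <- distribution %||% totals$total
  dist <- dist[!is.na(dist)]
  # mid-rank percentile: ties count half, so a threshold equal to the
  # distribution maximum still sits strictly below the 100th percentile
  pct <- 100 * (sum(dist < value) + 0.5 * sum(dist == value)) / length(dist)
  structure(
    list(value = value, percentile = pct,
         closures = closures, closure_totals = vals, n = length(dist)),
    class = "closure_threshold"
  )
}

normalize_closures <- function(closures) {
  if (is.data.frame(closures)) {
    stopifnot(all(c("year", "month") %in% names(closures)))
    return(tibble::as_tibble(closures[, c("year", "month")]))
  }
  dplyr::bind_rows(lapply(closures, function(x) {
    tibble::tibble(year = x[1], month = x[2])
  }))
}

#' @export
print.closure_threshold <- function(x, ...) {
  cat(sprintf(
    "<closure_threshold> %.3f degC anomaly (%.1fth percentile of %d 6-month means; %d historical closures)\n",
    x$value, x$percentile, x$n, nrow(x$closures)
  ))
  invisible(x)
}

#' Recommend a closure
#'
#' A closure is recommended when TOTAL meets or exceeds the threshold
#' (`>=` by default, so the historical closures that define the threshold
#' themselves trigger it).
#'
#' @param total TOTAL value(s) in degrees C.
#' @param threshold A [closure_threshold()] object or a numeric value.
#' @param comparator `"gte"` (default) or `"gt"`.
#' @return Logical vector.
#' @export
recommend_closure <- function(total, threshold, comparator = c("gte", "gt")) {
  comparator <- match.arg(comparator)
  thr <- if (inherits(threshold, "closure_threshold")) threshold$value else threshold
  if (comparator == "gte") total >= thr else total > thr
}

#' Forecast box-mean SSTA per ensemble member
#'
#' Anomalizes forecasts against their own (member, lead, month)
#' climatology over the box cells and averages spatially, one SSTA per
#' (member, init, lead).
#'
#' @inheritParams forecast_hci
#' @param box The monitoring box mask.
#' @return A tibble with `member`, `model`, `init`, `lead`, `target`,
#'   `target_year`, `target_month`, `ssta`.
#' @export
forecast_box_ssta <- function(forecasts, box, clim_years) {
  sub <- forecasts[forecasts$cell %in% box$cell, ]
  if (nrow(sub) == 0) stop("no forecast cells inside the box", call. = FALSE)
  clim <- sub[sub$target_year %in% clim_years, ] |>
    dplyr::group_by(member, lead, target_month, cell) |>
    dplyr::summarise(clim = mean(sst), .groups = "drop")
  sub |>
    dplyr::inner_join(clim, by = c("member", "lead", "target_month", "cell")) |>
    dplyr::group_by(member, model, init, lead, target, target_year,
                    target_month) |>
    dplyr::summarise(ssta = mean(sst - clim), .groups = "drop") |>
    dplyr::arrange(member, init, lead)
}

#' Forecast TOTAL from monthly-initialized ensembles
#'
#' For each member and initialization, the TOTAL forecast for a closure
#' month at lead `L` is the mean forecast SSTA over leads `L-6 ... L-1`
#' (the six months strictly preceding the closure month), so closure
#' forecasts exist at leads 6.5-11.5 months. Members are then averaged
#' into the ensemble mean.
#'
#' @inheritParams forecast_box_ssta
#' @param closure_months Candidate closure months (default June-August).
#' @param by_member Return per-member TOTAL values instead of the ensemble
#'   mean.
#' @return A tibble per (`target`, `lead`): `total`, `n_members` (or per
#'   member when `by_member = TRUE`).
#' @export
forecast_total <- function(forecasts, box, clim_years, closure_months = 6:8,
                           by_member = FALSE) {
  ssta <- forecast_box_ssta(forecasts, box, clim_years)
  per_member <- ssta |>
    dplyr::group_by(member, model, init) |>
    dplyr::arrange(lead, .by_group = TRUE) |>
    dplyr::mutate(total = trailing_mean6(ssta, lead)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(total), target_month %in% closure_months) |>
    dplyr::select(member, model, init, lead, target, target_year,
                  target_month, total)
  if (by_member) return(per_member)
  per_member |>
    dplyr::group_by(init, lead, target, target_year, target_month) |>
    dplyr::summarise(n_members = sum(!is.na(total)),
                     total = mean(total, na.rm = TRUE), .groups = "drop") |>
    dplyr::arrange(lead, target)
}

# Mean of the values at the six leads strictly preceding each lead;
# NA when the window is incomplete. `lead` must be sorted, step 1 month.
trailing_mean6 <- function(x, lead) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n >= 7 && all(abs(diff(lead) - 1) < 1e-9)) {
    cs <- cumsum(x)
    k <- 7:n
    out[k] <- (cs[k - 1] - c(0, cs)[k - 6]) / 6
  }
  out
}

#' Initialization coverage table for twice-yearly (downscaled) forecasts
#'
#' With initializations only in January and July, a closure month's six
#' preceding months are assembled from two runs: a June TOTAL uses
#' December from the previous July's initialization (lead 5.5) and
#' January-May from the January initialization (leads 0.5-4.5); July uses
#' January-June from the January initialization (leads 0.5-5.5); August
#' uses February-July (leads 1.5-6.5).
#'
#' @return A tibble with `closure_month`, `init_month`, `year_shift`
#'   (closure year minus initialization year) and `lead`.
#' @export
total_coverage_table <- function() {
  dplyr::bind_rows(
    tibble::tibble(closure_month = 6L, init_month = 7L, year_shift = 1L,
                   lead = 5.5),
    tibble::tibble(closure_month = 6L, init_month = 1L, year_shift = 0L,
                   lead = seq(0.5, 4.5, 1)),
    tibble::tibble(closure_month = 7L, init_month = 1L, year_shift = 0L,
                   lead = seq(0.5, 5.5, 1)),
    tibble::tibble(closure_month = 8L, init_month = 1L, year_shift = 0L,
                   lead = seq(1.5, 6.5, 1))
  )
}

#' Forecast TOTAL composed across initializations
#'
#' Implements the restricted bookkeeping for twice-yearly schedules: the
#' monthly SSTA values listed in a coverage table (by initialization month
#' and lead) are averaged into each closure month's TOTAL, per member,
#' then across members.
#'
#' @inheritParams forecast_total
#' @param coverage A coverage table, see [total_coverage_table()].
#' @return A tibble per (`target_year`, `closure_month`): `total`,
#'   `n_members`, `lead_max` (longest contributing lead).
#' @export
forecast_total_composite <- function(forecasts, box, clim_years,
                                     coverage = total_coverage_table(),
                                     by_member = FALSE) {
  ssta <- forecast_box_ssta(forecasts, box, clim_years) |>
    dplyr::mutate(init_month = lubridate::month(init),
                  init_year = lubridate::year(init))
  joined <- ssta |>
    dplyr::inner_join(coverage, by = c("init_month", "lead"),
                      relationship = "many-to-many") |>
    dplyr::mutate(closure_year = init_year + year_shift)
  n_needed <- coverage |>
    dplyr::count(closure_month, name = "n_needed")
  per_member <- joined |>
    dplyr::group_by(member, model, closure_year, closure_month) |>
    dplyr::summarise(total = mean(ssta), n_months = dplyr::n(),
                     lead_max = max(lead), .groups = "drop") |>
    dplyr::inner_join(n_needed, by = "closure_month") |>
    dplyr::filter(n_months == n_needed) |>
    dplyr::select(-n_months, -n_needed) |>
    dplyr::rename(target_year = closure_year, target_month = closure_month)
  if (by_member) return(per_member)
  per_member |>
    dplyr::group_by(target_year, target_month, lead_max) |>
    dplyr::summarise(n_members = dplyr::n(), total = mean(total),
                     .groups = "drop") |>
    dplyr::arrange(target_year, target_month)
}

#' Lead-specific forecast closure thresholds
#'
#' Converts the observed threshold percentile into a threshold on the
#' forecast scale, lead by lead: the threshold at lead L is the
#' percentile-matching quantile (linear interpolation, type 7) of the
#' ensemble-mean forecast TOTAL values at that lead.
#'
#' @param forecast_totals A [forecast_total()] tibble (ensemble means).
#' @param percentile Percentile on 0-100 (e.g. from [closure_threshold()]).
#' @return A tibble with `lead` and `threshold`.
#' @export
forecast_closure_thresholds <- function(forecast_totals, percentile) {
  stopifnot(percentile >= 0, percentile <= 100)
  forecast_totals |>
    dplyr::group_by(lead) |>
    dplyr::summarise(
      threshold = quantile(total, probs = percentile / 100, type = 7,
                           names = FALSE, na.rm = TRUE),
      .groups = "drop"
    )
}
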