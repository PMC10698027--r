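# Forecast engine: lead/target bookkeeping, per-member x lead drift
# correction, ensemble means, and the labelled forecast configurations
# (Global, Global Full, Global Reduced, Downscaled).

#' Target month of an initialization and lead
#'
#' Lead `k + 0.5` months targets the k-th calendar month after the
#' initialization month (mid-month convention): an initialization on
#' 1 January at lead 0.5 targets January itself, and at lead 11.5 targets
#' December of the same year.
#'
#' @param init Initialization date(s) (`Date`, first of month).
#' @param lead Lead time(s) in months (0.5, 1.5, ..., 11.5).
#' @return Target month(s) as `Date` (first of month).
#' @examples
#' lead_target(as.Date("2000-01-01"), c(0.5, 11.5))
#' @export
lead_target <- function(init, lead) {
  idx <- ym_index(lubridate::year(init), lubridate::month(init)) + floor(lead)
  ym_date(idx)
}

#' Per-member, per-lead monthly climatology
#'
#' The mean forecast SST for each (member, lead, calendar month, cell)
#' over the climatology years. Because a drifting model's bias grows with
#' lead, climatologies must be lead-specific: anomalies relative to them
#' remove the drift by construction.
#'
#' @param forecasts A forecast tibble (see [simulate_forecasts()]).
#' @param clim_years Years (of the target month) entering the climatology.
#' @return A tibble with `member`, `model`, `lead`, `target_month`, `cell`,
#'   `clim`, `n_years`.
#' @export
lead_climatology <- function(forecasts, clim_years) {
  cl <- forecasts[forecasts$target_year %in% clim_years, ] |>
    dplyr::group_by(member, model, lead, target_month, cell) |>
    dplyr::summarise(clim = mean(sst), n_years = dplyr::n(), .groups = "drop")
  have <- cl |> dplyr::distinct(member, lead, target_month)
  full <- tidyr::expand_grid(
    member = unique(forecasts$member),
    lead = unique(forecasts$lead),
    target_month = sort(unique(forecasts$target_month))
  )
  miss <- dplyr::anti_join(full, have, by = c("member", "lead", "target_month"))
  if (nrow(miss) > 0) {
    ex <- head(miss, 5)
    stop("insufficient coverage for the lead climatology; missing (member, ",
         "lead, month): ",
         paste(sprintf("(%s, %.1f, %d)", ex$member, ex$lead, ex$target_month),
               collapse = ", "),
         if (nrow(miss) > 5) sprintf(" and %d more", nrow(miss) - 5) else "",
         call. = FALSE)
  }
  cl
}

#' Anomalize forecasts against their own lead climatology
#'
#' Adds an `anom` column: forecast SST minus the (member, lead, month,
#' cell) climatology. Anomaly means over the climatology years are zero by
#' construction, so model drift is removed; applying the operation to
#' already-anomalized values leaves them unchanged (idempotence).
#'
#' @inheritParams lead_climatology
#' @param lead_clim Optional precomputed [lead_climatology()]; computed
#'   from `clim_years` when absent.
#' @return `forecasts` with an `anom` column.
#' @export
anomalize <- function(forecasts, lead_clim = NULL, clim_years = NULL) {
  if (is.null(lead_clim)) {
    if (is.null(clim_years)) {
      stop("supply either `lead_clim` or `clim_years`", call. = FALSE)
    }
    lead_clim <- lead_climatology(forecasts, clim_years)
  }
  out <- forecasts |>
    dplyr::left_join(
      lead_clim[, c("member", "lead", "target_month", "cell", "clim")],
      by = c("member", "lead", "target_month", "cell")
    )
  if (anyNA(out$clim)) {
    stop("lead climatology does not cover all forecast (member, lead, month, ",
         "cell) combinations", call. = FALSE)
  }
  dplyr::mutate(out, anom = sst - clim)
}

#' Ensemble mean of per-member series
#'
#' Unweighted mean across members at each time point. Members missing at
#' a time point are dropped from that point's mean (never imputed as 0).
#'
#' @param x A tibble of per-member values (one row per member and time).
#' @param value The value column (unquoted).
#' @param by Character vector of columns identifying a time point.
#' @return A tibble with `by` columns, `n_members` and the averaged value.
#' @examples
#' # ensemble_mean(per_member_hci, hci, by = c("target", "lead"))
#' @export
ensemble_mean <- function(x, value,
                          by = c("target", "target_year", "target_month",
                                 "lead")) {
  if (nrow(x) == 0) stop("no member series to average", call. = FALSE)
  v <- enquo(value)
  nm <- as_name(v)
  by <- intersect(by, names(x))
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n_members = sum(!is.na(!!v)),
                     !!nm := mean(!!v, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(!!nm := ifelse(is.nan(.data[[nm]]), NA_real_, .data[[nm]]))
}

#' Assemble the four labelled forecast configurations
#'
#' Builds the retrospective-forecast configurations compared in the
#' analysis: `Global` (the full ensemble over the full evaluation span),
#' `GlobalFull` (full ensemble, comparison span), `GlobalReduced` (a
#' 3-member subset of the global ensemble, comparison span) and
#' `Downscaled` (a separately produced 3-member ensemble initialized in
#' January and July). When a downscaled set is present, the comparison
#' configurations are restricted to its January/July initializations so
#' the four are evaluated on a common footing.
#'
#' @param global Forecast tibble for the full global ensemble.
#' @param downscaled Forecast tibble for the downscaled ensemble (must be
#'   initialized in January and July only).
#' @param reduced_members Member ids of the reduced subset; must be a
#'   subset of the global member ids. Defaults to the 2nd, 8th and 10th
#'   global member when available, else the first three.
#' @param full_years Evaluation/climatology years for `Global`.
#' @param comparison_years Climatology years shared by `GlobalFull`,
#'   `GlobalReduced` and `Downscaled` (a 1981-2010-style reduced span).
#' @return A named list of configurations (class `ensemble_configs`), each
#'   with `name`, `forecasts`, `clim_years`, `init_months`, `n_members`.
#' @export
build_configurations <- function(global, downscaled,
                                 reduced_members = NULL,
                                 full_years, comparison_years) {
  g_members <- sort(unique(global$member))
  if (is.null(reduced_members)) {
    reduced_members <- if (length(g_members) >= 10) {
      g_members[c(2, 8, 10)]
    } else {
      g_members[seq_len(min(3, length(g_members)))]
    }
  }
  if (!all(reduced_members %in% g_members)) {
    stop("`reduced_members` must be a subset of the global member ids",
         call. = FALSE)
  }
  ds_months <- sort(unique(lubridate::month(downscaled$init)))
  if (!all(ds_months %in% c(1L, 7L))) {
    stop("downscaled forecasts must be initialized in January and July only",
         call. = FALSE)
  }
  g_cmp <- global |>
    dplyr::filter(lubridate::month(init) %in% ds_months,
                  lubridate::year(init) %in% comparison_years)
  cfg <- function(name, fc, clim_years, init_months) {
    structure(
      list(name = name, forecasts = fc, clim_years = clim_years,
           init_months = init_months,
           n_members = dplyr::n_distinct(fc$member)),
      class = "ensemble_config"
    )
  }
  out <- list(
    Global = cfg("Global", global, full_years,
                 sort(unique(lubridate::month(global$init)))),
    GlobalFull = cfg("GlobalFull", g_cmp, comparison_years, ds_months),
    GlobalReduced = cfg(
      "GlobalReduced",
      dplyr::filter(g_cmp, member %in% reduced_members),
      comparison_years, ds_months
    ),
    Downscaled = cfg("Downscaled",
                     dplyr::filter(downscaled,
                                   lubridate::year(init) %in% comparison_years),
                     comparison_years, ds_months)
  )
  class(out) <- "ensemble_configs"
  out
}

#' @export
print.ensemble_config <- function(x, ...) {
  cat(sprintf(
    "<ensemble_config> %s: %d members, climatology %d-%d, init months %s\n",
    x$name, x$n_members, min(x$clim_years), max(x$clim_years),
    paste(x$init_months, collapse = ",")
  ))
  invisible(x)
}

#' @export
print.ensemble_configs <- function(x, ...) {
  for (cf in x) print(cf)
  invisible(x)
}

#' Skill of the Habitat Compression Index across forecast configurations
#'
#' For each configuration, computes observed and forecast HCI with the
#' configuration's own climatology years, joins them by target month and
#' lead, and evaluates the verification suite. The result is a tidy table
#' ready for the configuration box-plot comparison.
#'
#' @param configs An [build_configurations()] object (or a named list of
#'   configurations).
#' @param observed Observed SST tibble.
#' @param band75,band150 HCI bands.
#' @param n_boot Bootstrap replicates for the categorical significance
#'   flags (0 skips bootstrapping).
#' @param seed Optional seed for the bootstrap.
#' @return A tibble of per-(config, target month, lead) skill metrics.
#' @export
configuration_skill <- function(configs, observed, band75, band150,
                                n_boot = 0, seed = NULL) {
  purrr::map_dfr(configs, function(cf) {
    thr <- monthly_thresholds(observed, band75, cf$clim_years)
    obs_idx <- hci_series(observed, thr, band150) |>
      classify_high_compression(clim_years = cf$clim_years)
    fc_idx <- forecast_hci(cf$forecasts, band75, band150, cf$clim_years)
    joined <- dplyr::inner_join(
      dplyr::select(obs_idx, year, month, obs_hci = hci, obs_event = event),
      dplyr::select(fc_idx, target_year, target_month, lead,
                    fc_hci = hci, fc_event = event),
      by = c("year" = "target_year", "month" = "target_month")
    )
    skill_report(joined, obs = obs_hci, fcst = fc_hci,
                 obs_event = obs_event, fcst_event = fc_event,
                 by = c("month", "lead"), time = "year",
                 n_boot = n_boot, seed = seed) |>
      dplyr::mutate(config = cf$name, .before = 1)
  })
}
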