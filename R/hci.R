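# Habitat Compression Index: the fraction of coastal-band cells colder
# than a monthly climatological threshold. Low values mean the cool
# upwelling habitat is squeezed against the shore (elevated whale
# entanglement risk); "high compression" events are months at or below
# the long-term mean of the index.

#' Monthly SST thresholds for the Habitat Compression Index
#'
#' The threshold for calendar month m is the mean SST over the inner
#' coastal band (classically, coast to 75 km) across the climatology
#' years, one value per month.
#'
#' @param sst SST tibble with `year`, `month`, `cell`, `sst` (e.g. from
#'   [simulate_observed_sst()]).
#' @param band A [coastal_band()] mask (the inner, threshold band).
#' @param clim_years Climatology years (e.g. `1981:2010`). Every month of
#'   every climatology year must be present.
#' @return A tibble with columns `month` (1-12) and `threshold` (degrees C).
#' @export
monthly_thresholds <- function(sst, band, clim_years) {
  stopifnot(nrow(band) > 0)
  sub <- sst[sst$cell %in% band$cell & sst$year %in% clim_years, ]
  present <- unique(sub[, c("year", "month")])
  missing_n <- length(clim_years) * 12L - nrow(present)
  if (missing_n > 0) {
    stop("SST series is missing ", missing_n,
         " (year, month) combinations inside the climatology years",
         call. = FALSE)
  }
  sub |>
    dplyr::group_by(month) |>
    dplyr::summarise(threshold = mean(sst), .groups = "drop")
}

#' Habitat Compression Index for one set of SST values
#'
#' The fraction of band cells strictly colder than the threshold. Missing
#' cells are ignored; if every value is missing the index is `NA`, never 0.
#'
#' @param sst_values SST values (degrees C) for the cells of the 150 km band.
#' @param threshold The monthly threshold (degrees C).
#' @return A value in \[0, 1\], or `NA` when undefined.
#' @examples
#' compute_hci(c(11, 12, 14, 15), threshold = 13)  # 0.5
#' @export
compute_hci <- function(sst_values, threshold) {
  ok <- !is.na(sst_values)
  if (!any(ok)) return(NA_real_)
  mean(sst_values[ok] < threshold)
}

#' Habitat Compression Index time series
#'
#' Computes the HCI for every month of an SST series: the fraction of
#' 150 km-band cells with SST strictly below that calendar month's
#' threshold.
#'
#' @inheritParams monthly_thresholds
#' @param thresholds A [monthly_thresholds()] tibble.
#' @param band The outer (150 km) band the index is evaluated over.
#' @return A tibble with `date`, `year`, `month`, `n_cells`, `hci`.
#' @export
hci_series <- function(sst, thresholds, band) {
  stopifnot(all(c("month", "threshold") %in% names(thresholds)),
            nrow(band) > 0)
  sst[sst$cell %in% band$cell, ] |>
    dplyr::inner_join(thresholds, by = "month") |>
    dplyr::group_by(date, year, month) |>
    dplyr::summarise(
      n_cells = sum(!is.na(sst)),
      hci = compute_hci(sst, threshold[1]),
      .groups = "drop"
    ) |>
    dplyr::arrange(date)
}

#' Classify high-compression events
#'
#' Flags months whose index value is below or equal to a long-term
#' reference mean (the management rule for whale entanglement risk). The
#' reference defaults to the mean of the series over the climatology
#' years; for forecasts it should be lead-specific, which happens
#' automatically when the input has a `lead` column.
#'
#' @param index A tibble with a `hci` (or `value`) column and `year`.
#' @param reference Optional fixed reference mean; overrides `clim_years`.
#' @param clim_years Years over which to compute the reference mean.
#' @param comparator `"lte"` (event when value <= mean, the management
#'   reading) or `"lt"`.
#' @return The input with `ref_mean` and logical `event` columns; the rule
#'   is recorded in the `event_rule` attribute.
#' @export
classify_high_compression <- function(index, reference = NULL,
                                      clim_years = NULL,
                                      comparator = c("lte", "lt")) {
  comparator <- match.arg(comparator)
  val_col <- if ("hci" %in% names(index)) "hci" else "value"
  stopifnot(val_col %in% names(index))
  by_lead <- "lead" %in% names(index)

  if (!is.null(reference)) {
    index$ref_mean <- reference
  } else {
    if (is.null(clim_years)) {
      stop("supply either `reference` or `clim_years`", call. = FALSE)
    }
    grouping <- if (by_lead) "lead" else character()
    ref <- index[index$year %in% clim_years, ] |>
      dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
      dplyr::summarise(ref_mean = mean(.data[[val_col]], na.rm = TRUE),
                       .groups = "drop")
    if (nrow(ref) == 0 || anyNA(ref$ref_mean) || any(is.nan(ref$ref_mean))) {
      stop("reference mean undefined: no index values in `clim_years`",
           call. = FALSE)
    }
    index <- if (by_lead) {
      dplyr::left_join(index, ref, by = "lead")
    } else {
      dplyr::mutate(index, ref_mean = ref$ref_mean[1])
    }
  }
  v <- index[[val_col]]
  index$event <- if (comparator == "lte") v <= index$ref_mean else v < index$ref_mean
  attr(index, "event_rule") <- sprintf(
    "high compression: value %s long-term mean%s",
    if (comparator == "lte") "<=" else "<",
    if (by_lead) " (lead-specific)" else ""
  )
  index
}

#' Forecast Habitat Compression Index
#'
#' Runs the HCI through a forecast ensemble the way a retrospective
#' forecast would: monthly thresholds are computed separately for each
#' ensemble member and each lead time over the climatology years (which
#' absorbs model drift), the index is computed per member over the 150 km
#' band, members are averaged into an ensemble mean, and events are
#' classified against a lead-specific long-term mean of the ensemble
#' index.
#'
#' @param forecasts A [simulate_forecasts()] tibble (columns `init`,
#'   `lead`, `target`, `target_year`, `target_month`, `member`, `cell`,
#'   `sst`).
#' @param band75,band150 Inner (threshold) and outer (index) coastal bands.
#' @param clim_years Climatology years for thresholds and the event
#'   reference mean.
#' @param comparator Event comparator, see [classify_high_compression()].
#' @param by_member Return per-member index values instead of the ensemble
#'   mean (no event classification).
#' @return A tibble per (`target`, `lead`): `hci` (ensemble mean),
#'   `n_members`, `ref_mean`, `event`; or per member when
#'   `by_member = TRUE`.
#' @export
forecast_hci <- function(forecasts, band75, band150, clim_years,
                         comparator = c("lte", "lt"), by_member = FALSE) {
  comparator <- match.arg(comparator)
  f75 <- forecasts[forecasts$cell %in% band75$cell, ]
  if (nrow(f75) == 0) stop("no forecast cells inside the 75 km band", call. = FALSE)

  thr <- f75[f75$target_year %in% clim_years, ] |>
    dplyr::group_by(member, lead, target_month) |>
    dplyr::summarise(threshold = mean(sst), .groups = "drop")
  needed <- dplyr::distinct(f75, member, lead, target_month)
  miss <- dplyr::anti_join(needed, thr, by = c("member", "lead", "target_month"))
  if (nrow(miss) > 0) {
    stop("forecast coverage too thin: some (member, lead, month) has no ",
         "target inside the climatology years", call. = FALSE)
  }

  per_member <- forecasts[forecasts$cell %in% band150$cell, ] |>
    dplyr::inner_join(thr, by = c("member", "lead", "target_month")) |>
    dplyr::group_by(member, model, init, lead, target, target_year,
                    target_month) |>
    dplyr::summarise(hci = compute_hci(sst, threshold[1]), .groups = "drop")
  if (by_member) {
    return(dplyr::arrange(per_member, member, lead, target))
  }

  ens <- per_member |>
    dplyr::group_by(init, lead, target, target_year, target_month) |>
    dplyr::summarise(n_members = sum(!is.na(hci)),
                     hci = mean(hci, na.rm = TRUE), .groups = "drop") |>
    dplyr::mutate(hci = ifelse(is.nan(hci), NA_real_, hci)) |>
    dplyr::rename(year = target_year)

  out <- classify_high_compression(ens, clim_years = clim_years,
                                   comparator = comparator)
  out |>
    dplyr::rename(target_year = year) |>
    dplyr::arrange(lead, target)
}
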