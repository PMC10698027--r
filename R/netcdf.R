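# CF-style netCDF readers/writers for gridded fields. CSV remains the
# exchange format for index and skill tables; netCDF is used only where
# the data are genuinely gridded.

require_ncdf4 <- function() {
  if (!requireNamespace("ncdf4", quietly = TRUE)) {
    stop("the `ncdf4` package is required for netCDF input/output",
         call. = FALSE)
  }
}

ACCEPTED_SST_UNITS <- c("degC", "degrees_C", "degree_C", "celsius", "Celsius")

#' Write an SST series as CF-style netCDF
#'
#' Dimensions `lon`, `lat`, `time` (days since 1970-01-01); variables
#' `sst` (degC, land as fill), `land_mask` (byte) and `coast_km`.
#'
#' @param sst SST tibble (`date`, `year`, `month`, `cell`, `sst`).
#' @param grid The [make_grid()] grid the series lives on.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sst_netcdf <- function(sst, grid, path) {
  require_ncdf4()
  lons <- sort(unique(grid$lon))
  lats <- sort(unique(grid$lat))
  dates <- sort(unique(sst$date))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", lons)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", lats)
  dim_time <- ncdf4::ncdim_def("time", "days since 1970-01-01",
                               as.numeric(dates), unlim = TRUE,
                               calendar = "standard")
  fill <- 1e30
  var_sst <- ncdf4::ncvar_def("sst", "degC", list(dim_lon, dim_lat, dim_time),
                              missval = fill, prec = "double",
                              longname = "sea surface temperature")
  var_land <- ncdf4::ncvar_def("land_mask", "1", list(dim_lon, dim_lat),
                               prec = "byte", longname = "1 = land")
  var_coast <- ncdf4::ncvar_def("coast_km", "km", list(dim_lon, dim_lat),
                                missval = fill, prec = "double",
                                longname = "distance to coastline")
  nc <- ncdf4::nc_create(path, list(var_sst, var_land, var_coast))
  on.exit(ncdf4::nc_close(nc), add = TRUE)

  i <- match(grid$lon, lons)
  j <- match(grid$lat, lats)
  land_arr <- matrix(0L, length(lons), length(lats))
  land_arr[cbind(i, j)] <- as.integer(grid$land)
  coast_arr <- matrix(NA_real_, length(lons), length(lats))
  coast_arr[cbind(i, j)] <- grid$coast_km

  arr <- array(NA_real_, c(length(lons), length(lats), length(dates)))
  gi <- match(sst$cell, grid$cell)
  arr[cbind(i[gi], j[gi], match(sst$date, dates))] <- sst$sst

  ncdf4::ncvar_put(nc, var_sst, arr)
  ncdf4::ncvar_put(nc, var_land, land_arr)
  ncdf4::ncvar_put(nc, var_coast, coast_arr)
  ncdf4::ncatt_put(nc, 0, "Conventions", "CF-1.8")
  invisible(path)
}

#' Read an SST series from CF-style netCDF
#'
#' Validates the schema (dimensions `lon`, `lat`, `time` and a temperature
#' variable in degrees Celsius; Fahrenheit or missing units are rejected)
#' and reconstructs the grid and the long SST tibble.
#'
#' @param path A file written by [write_sst_netcdf()] (or any CF file with
#'   the same layout).
#' @return A list with elements `grid` (a `coast_grid` tibble) and `sst`.
#' @export
read_sst_netcdf <- function(path) {
  require_ncdf4()
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  need <- c("lon", "lat", "time")
  if (!all(need %in% names(nc$dim))) {
    stop("schema error: file must have lon, lat and time dimensions",
         call. = FALSE)
  }
  if (!"sst" %in% names(nc$var)) {
    stop("schema error: no `sst` variable", call. = FALSE)
  }
  units <- ncdf4::ncatt_get(nc, "sst", "units")$value
  if (!units %in% ACCEPTED_SST_UNITS) {
    stop("schema error: sst units must be degrees Celsius, got `",
         units, "`", call. = FALSE)
  }
  lons <- as.numeric(nc$dim$lon$vals)
  lats <- as.numeric(nc$dim$lat$vals)
  dates <- as.Date(as.numeric(nc$dim$time$vals), origin = "1970-01-01")
  arr <- ncdf4::ncvar_get(nc, "sst", collapse_degen = FALSE)
  land_arr <- if ("land_mask" %in% names(nc$var)) {
    ncdf4::ncvar_get(nc, "land_mask", collapse_degen = FALSE)
  } else {
    matrix(0L, length(lons), length(lats))
  }
  coast_arr <- if ("coast_km" %in% names(nc$var)) {
    ncdf4::ncvar_get(nc, "coast_km", collapse_degen = FALSE)
  } else {
    matrix(NA_real_, length(lons), length(lats))
  }

  cells <- tidyr::expand_grid(lat = lats, lon = lons)
  i <- match(cells$lon, lons)
  j <- match(cells$lat, lats)
  grid <- tibble::tibble(
    cell = seq_len(nrow(cells)), lon = cells$lon, lat = cells$lat,
    land = as.logical(land_arr[cbind(i, j)]),
    coast_km = coast_arr[cbind(i, j)]
  )
  res <- if (length(lons) > 1) diff(sort(lons))[1] else NA_real_
  attr(grid, "resolution") <- res
  attr(grid, "lat_range") <- range(lats) + c(-res / 2, res / 2)
  attr(grid, "lon_range") <- range(lons) + c(-res / 2, res / 2)
  class(grid) <- c("coast_grid", class(grid))

  ocean <- which(!grid$land)
  sst <- tidyr::expand_grid(cell = grid$cell[ocean],
                            date = dates) |>
    dplyr::arrange(cell, date)
  sst$sst <- arr[cbind(
    rep(i[ocean], each = length(dates)),
    rep(j[ocean], each = length(dates)),
    rep(seq_along(dates), times = length(ocean))
  )]
  sst <- sst |>
    dplyr::mutate(year = lubridate::year(date),
                  month = lubridate::month(date)) |>
    dplyr::select(date, year, month, cell, sst)
  list(grid = grid, sst = sst)
}

#' Write a forecast set as CF-style netCDF
#'
#' Dimensions `lon`, `lat`, `lead` (months), `member` and `init` (days
#' since 1970-01-01); variable `sst` in degC. Member ids and model labels
#' are stored as global attributes.
#'
#' @param forecasts A [simulate_forecasts()] tibble.
#' @param grid The grid the forecasts live on.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_forecast_netcdf <- function(forecasts, grid, path) {
  require_ncdf4()
  lons <- sort(unique(grid$lon))
  lats <- sort(unique(grid$lat))
  leads <- sort(unique(forecasts$lead))
  members <- sort(unique(forecasts$member))
  inits <- sort(unique(forecasts$init))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", lons)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", lats)
  dim_lead <- ncdf4::ncdim_def("lead", "months", leads)
  dim_member <- ncdf4::ncdim_def("member", "1", seq_along(members))
  dim_init <- ncdf4::ncdim_def("init", "days since 1970-01-01",
                               as.numeric(inits), calendar = "standard")
  fill <- 1e30
  var_sst <- ncdf4::ncvar_def(
    "sst", "degC", list(dim_lon, dim_lat, dim_lead, dim_member, dim_init),
    missval = fill, prec = "double",
    longname = "forecast sea surface temperature"
  )
  nc <- ncdf4::nc_create(path, list(var_sst))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  arr <- array(NA_real_, c(length(lons), length(lats), length(leads),
                           length(members), length(inits)))
  arr[cbind(match(grid$lon[match(forecasts$cell, grid$cell)], lons),
            match(grid$lat[match(forecasts$cell, grid$cell)], lats),
            match(forecasts$lead, leads),
            match(forecasts$member, members),
            match(forecasts$init, inits))] <- forecasts$sst
  ncdf4::ncvar_put(nc, var_sst, arr)
  ncdf4::ncatt_put(nc, 0, "Conventions", "CF-1.8")
  ncdf4::ncatt_put(nc, 0, "member_ids", paste(members, collapse = ","))
  models <- forecasts |> dplyr::distinct(member, model) |> dplyr::arrange(member)
  ncdf4::ncatt_put(nc, 0, "member_models", paste(models$model, collapse = ","))
  invisible(path)
}

#' Read a forecast set from CF-style netCDF
#'
#' @param path A file written by [write_forecast_netcdf()].
#' @return A forecast tibble with target months recomputed from
#'   initialization and lead.
#' @export
read_forecast_netcdf <- function(path) {
  require_ncdf4()
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  need <- c("lon", "lat", "lead", "member", "init")
  if (!all(need %in% names(nc$dim))) {
    stop("schema error: file must have lon, lat, lead, member and init ",
         "dimensions", call. = FALSE)
  }
  units <- ncdf4::ncatt_get(nc, "sst", "units")$value
  if (!units %in% ACCEPTED_SST_UNITS) {
    stop("schema error: sst units must be degrees Celsius, got `",
         units, "`", call. = FALSE)
  }
  lons <- as.numeric(nc$dim$lon$vals)
  lats <- as.numeric(nc$dim$lat$vals)
  leads <- as.numeric(nc$dim$lead$vals)
  inits <- as.Date(as.numeric(nc$dim$init$vals), origin = "1970-01-01")
  members <- strsplit(ncdf4::ncatt_get(nc, 0, "member_ids")$value, ",")[[1]]
  models <- strsplit(ncdf4::ncatt_get(nc, 0, "member_models")$value, ",")[[1]]
  arr <- ncdf4::ncvar_get(nc, "sst", collapse_degen = FALSE)

  cells <- tidyr::expand_grid(lat = lats, lon = lons) |>
    dplyr::mutate(cell = dplyr::row_number())
  full <- tidyr::expand_grid(
    init = inits, member_i = seq_along(members), lead = leads,
    cell = cells$cell
  )
  ci <- match(cells$lon[full$cell], lons)
  cj <- match(cells$lat[full$cell], lats)
  full$sst <- arr[cbind(ci, cj, match(full$lead, leads), full$member_i,
                        match(full$init, inits))]
  full |>
    dplyr::filter(!is.na(sst)) |>
    dplyr::mutate(
      member = members[member_i],
      model = models[member_i],
      target = lead_target(init, lead),
      target_year = lubridate::year(target),
      target_month = lubridate::month(target)
    ) |>
    dplyr::select(init, lead, target, target_year, target_month, member,
                  model, cell, sst)
}

#' Write a region mask as netCDF byte array
#'
#' @param mask A [coastal_band()] or [region_box()] mask.
#' @param grid The full grid the mask was cut from.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mask_netcdf <- function(mask, grid, path) {
  require_ncdf4()
  lons <- sort(unique(grid$lon))
  lats <- sort(unique(grid$lat))
  dim_lon <- ncdf4::ncdim_def("lon", "degrees_east", lons)
  dim_lat <- ncdf4::ncdim_def("lat", "degrees_north", lats)
  var_m <- ncdf4::ncvar_def("mask", "1", list(dim_lon, dim_lat),
                            prec = "byte", longname = attr(mask, "descriptor"))
  nc <- ncdf4::nc_create(path, list(var_m))
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  arr <- matrix(0L, length(lons), length(lats))
  arr[cbind(match(grid$lon, lons), match(grid$lat, lats))] <-
    as.integer(grid$cell %in% mask$cell)
  ncdf4::ncvar_put(nc, var_m, arr)
  invisible(path)
}
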