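# Region masks: coastal distance bands and latitude/longitude boxes.
# Membership is decided by cell centre, bounds are closed intervals, and
# masks never include land cells.

new_region_mask <- function(cells, descriptor) {
  out <- tibble::as_tibble(cells)
  attr(out, "descriptor") <- descriptor
  class(out) <- c("region_mask", class(out))
  out
}

#' Coastal distance-band mask
#'
#' Selects the ocean cells whose centre lies within `max_km` of the
#' coastline and within a latitude range. The Habitat Compression Index
#' uses two such bands off California (35-40 N): SST thresholds come from
#' the 75 km band, the index itself is evaluated over the 150 km band.
#'
#' @param grid A [make_grid()] grid.
#' @param max_km Maximum distance to the coastline in km (> 0; `Inf` keeps
#'   every ocean cell in the latitude range).
#' @param lat_min,lat_max Closed latitude bounds in degrees north.
#' @return A `region_mask` tibble: the qualifying rows of `grid`.
#' @examples
#' g <- make_grid(c(34, 41), c(-126, -120), resolution = 1)
#' band75 <- coastal_band(g, 75, 35, 40)
#' band150 <- coastal_band(g, 150, 35, 40)
#' all(band75$cell %in% band150$cell)
#' @export
coastal_band <- function(grid, max_km, lat_min = -90, lat_max = 90) {
  stopifnot(inherits(grid, "coast_grid"))
  if (!is.numeric(max_km) || max_km <= 0) {
    stop("`max_km` must be a positive distance in km", call. = FALSE)
  }
  if (lat_min >= lat_max) stop("`lat_min` must be below `lat_max`", call. = FALSE)
  keep <- !grid$land & grid$coast_km <= max_km &
    grid$lat >= lat_min & grid$lat <= lat_max
  if (!any(keep)) {
    stop(sprintf(
      "no ocean cell within %g km of the coast in %g..%g N: band mask is empty",
      max_km, lat_min, lat_max
    ), call. = FALSE)
  }
  new_region_mask(
    grid[keep, ],
    sprintf("coastal band <= %g km, lat [%g, %g]", max_km, lat_min, lat_max)
  )
}

#' Latitude/longitude box mask
#'
#' Selects ocean cells whose centre lies inside a closed lat/lon box, e.g.
#' the Southern California Bight (31-34 N, 120-116 W) monitored by the
#' loggerhead closure indicator.
#'
#' @inheritParams coastal_band
#' @param lon_min,lon_max Closed longitude bounds, degrees east (-180..180).
#' @return A `region_mask` tibble.
#' @export
region_box <- function(grid, lat_min, lat_max, lon_min, lon_max) {
  stopifnot(inherits(grid, "coast_grid"))
  if (lat_min >= lat_max) stop("`lat_min` must be below `lat_max`", call. = FALSE)
  lon_min <- wrap_lon(lon_min)
  lon_max <- wrap_lon(lon_max)
  if (lon_min >= lon_max) stop("`lon_min` must be west of `lon_max`", call. = FALSE)
  keep <- !grid$land &
    grid$lat >= lat_min & grid$lat <= lat_max &
    grid$lon >= lon_min & grid$lon <= lon_max
  if (!any(keep)) {
    stop("no ocean cell inside the requested box: mask is empty", call. = FALSE)
  }
  new_region_mask(
    grid[keep, ],
    sprintf("box lat [%g, %g], lon [%g, %g]", lat_min, lat_max, lon_min, lon_max)
  )
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %s: %d cells\n", attr(x, "descriptor"), nrow(x)))
  NextMethod()
}
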