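# Ocean grid with distance-to-coast, the spatial scaffold for the
# distance-band and box masks.

#' Build a rectangular ocean grid with distance to a synthetic coastline
#'
#' Lays a regular latitude-longitude mesh of cell centres over a bounding
#' box, marks land cells, and computes every ocean cell's great-circle
#' distance to the coastline (haversine on a sphere of radius 6371 km).
#' The default coastline is a meridian at the eastern edge of the domain,
#' which mimics a north-south shore such as the U.S. West Coast: the whole
#' mesh is then ocean and distance-to-coast grows westward. A custom land
#' mask may be supplied instead, in which case the coastline is the set of
#' edges shared by an ocean cell and a land cell.
#'
#' @param lat_range,lon_range Numeric length-2 bounds in degrees north /
#'   degrees east (-180..180). Defaults cover the California Current domain
#'   (30-48 N, 134-115.5 W).
#' @param resolution Cell size in degrees. The indices aggregate over broad
#'   coastal bands, so coarse grids (0.5-2 degrees) are adequate and fast;
#'   note that a resolution above ~1.3 degrees leaves no cell centre within
#'   75 km of the coast.
#' @param coast_lon Longitude of the synthetic meridian coastline. Defaults
#'   to the eastern edge of `lon_range`. Cells with centres east of it are
#'   land. Ignored when `land_mask` is given and marks at least one land cell.
#' @param land_mask Optional logical vector (one value per cell, in grid row
#'   order: latitude-major, longitude varying fastest) or a
#'   `function(lon, lat)` returning `TRUE` for land.
#' @param coast_sample Spacing in degrees at which the coastline is sampled
#'   into points for the nearest-distance search.
#'
#' @return A tibble of class `coast_grid` with one row per cell:
#'   `cell` (integer id), `lon`, `lat` (cell-centre degrees), `land`
#'   (logical) and `coast_km` (km to the nearest coastline point; `NA` for
#'   land cells).
#'
#' @examples
#' g <- make_grid(c(34, 40), c(-126, -120), resolution = 1)
#' dplyr::filter(g, coast_km <= 150)
#' @export
make_grid <- function(lat_range = c(30, 48),
                      lon_range = c(-134, -115.5),
                      resolution = 1,
                      coast_lon = NULL,
                      land_mask = NULL,
                      coast_sample = resolution / 10) {
  stopifnot(length(lat_range) == 2, length(lon_range) == 2, resolution > 0)
  lat_range <- sort(as.numeric(lat_range))
  lon_range <- sort(wrap_lon(as.numeric(lon_range)))
  lats <- seq(lat_range[1] + resolution / 2, lat_range[2] - resolution / 2 + 1e-9,
              by = resolution)
  lons <- seq(lon_range[1] + resolution / 2, lon_range[2] - resolution / 2 + 1e-9,
              by = resolution)
  if (length(lats) < 2 || length(lons) < 2) {
    stop("grid must have at least 2 cells per axis; decrease `resolution`",
         call. = FALSE)
  }
  cells <- tidyr::expand_grid(lat = lats, lon = lons)
  if (is.null(coast_lon)) coast_lon <- lon_range[2]

  if (is.null(land_mask)) {
    land <- cells$lon > coast_lon
  } else if (is.function(land_mask)) {
    land <- as.logical(land_mask(cells$lon, cells$lat))
  } else {
    land <- as.logical(land_mask)
    if (length(land) != nrow(cells)) {
      stop("`land_mask` must have one value per cell (", nrow(cells), ")",
           call. = FALSE)
    }
  }
  land[is.na(land)] <- FALSE
  if (all(land)) stop("empty ocean domain: every cell is land", call. = FALSE)

  coast <- coastline_points(cells, land, resolution, coast_lon, lat_range,
                            coast_sample)
  dmat <- geosphere::distm(as.matrix(cells[!land, c("lon", "lat")]),
                           as.matrix(coast[, c("lon", "lat")]),
                           fun = haversine_m)
  coast_km <- rep(NA_real_, nrow(cells))
  coast_km[!land] <- apply(dmat, 1, min) / 1000

  out <- tibble::tibble(
    cell = seq_len(nrow(cells)),
    lon = cells$lon, lat = cells$lat,
    land = land, coast_km = coast_km
  )
  attr(out, "resolution") <- resolution
  attr(out, "lat_range") <- lat_range
  attr(out, "lon_range") <- lon_range
  attr(out, "coast_lon") <- coast_lon
  class(out) <- c("coast_grid", class(out))
  out
}

# Haversine distance in metres on the R = 6371 km sphere.
haversine_m <- function(p1, p2) geosphere::distHaversine(p1, p2, r = 6371000)

# Sample the coastline into points. Meridian rule: points along the
# coastal meridian spanning the domain's latitude range. Custom mask:
# points along every edge shared by an ocean cell and a land cell.
coastline_points <- function(cells, land, resolution, coast_lon, lat_range,
                             coast_sample) {
  if (!any(land)) {
    return(tibble::tibble(
      lon = coast_lon,
      lat = seq(lat_range[1], lat_range[2], by = coast_sample)
    ))
  }
  lats <- sort(unique(cells$lat))
  lons <- sort(unique(cells$lon))
  li <- match(cells$lat, lats)
  lj <- match(cells$lon, lons)
  is_land <- matrix(FALSE, length(lats), length(lons))
  is_land[cbind(li, lj)] <- land
  half <- resolution / 2
  n_sub <- max(2L, ceiling(resolution / coast_sample) + 1L)
  edge_pts <- list()
  for (i in seq_along(lats)) {
    for (j in seq_along(lons)) {
      if (is_land[i, j]) next
      # east / west neighbours -> vertical (meridian) edge segments
      for (dj in c(-1L, 1L)) {
        jj <- j + dj
        if (jj >= 1 && jj <= length(lons) && is_land[i, jj]) {
          edge_pts[[length(edge_pts) + 1L]] <- tibble::tibble(
            lon = lons[j] + dj * half,
            lat = seq(lats[i] - half, lats[i] + half, length.out = n_sub)
          )
        }
      }
      # north / south neighbours -> horizontal (parallel) edge segments
      for (di in c(-1L, 1L)) {
        ii <- i + di
        if (ii >= 1 && ii <= length(lats) && is_land[ii, j]) {
          edge_pts[[length(edge_pts) + 1L]] <- tibble::tibble(
            lon = seq(lons[j] - half, lons[j] + half, length.out = n_sub),
            lat = lats[i] + di * half
          )
        }
      }
    }
  }
  if (length(edge_pts) == 0) {
    stop("land mask has no ocean-land boundary inside the domain; ",
         "cannot locate a coastline", call. = FALSE)
  }
  dplyr::distinct(dplyr::bind_rows(edge_pts))
}

#' @export
print.coast_grid <- function(x, ...) {
  n_ocean <- sum(!x$land)
  cat(sprintf(
    "<coast_grid> %d cells (%d ocean), %.2f deg resolution, lat %g..%g, lon %g..%g\n",
    nrow(x), n_ocean, attr(x, "resolution"),
    attr(x, "lat_range")[1], attr(x, "lat_range")[2],
    attr(x, "lon_range")[1], attr(x, "lon_range")[2]
  ))
  NextMethod()
}
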