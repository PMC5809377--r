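# Regular lat/lon grids and gridded scalar fields.
#
# Fields are stored as n_lat x n_lon matrices with row 1 at lat_min (south).
# Cell areas follow the spherical formula, so they shrink towards the poles.

EARTH_RADIUS_KM <- 6371.0

#' Define a regular latitude/longitude grid
#'
#' A grid of `n_lat` x `n_lon` equally spaced cells covering the bounding box
#' `[lat_min, lat_max] x [lon_min, lon_max]` (degrees). Cell areas are exact
#' spherical-band areas and therefore decrease with |latitude|.
#'
#' @param n_lat,n_lon Number of cells in latitude/longitude (>= 1).
#' @param lat_min,lat_max,lon_min,lon_max Bounding box in degrees.
#' @return A `grid_spec` object with cell-centre coordinates (`lat`, `lon`)
#'   and per-row cell areas in km^2 (`cell_area_row`).
#' @export
grid_spec <- function(n_lat, n_lon,
                      lat_min = 6, lat_max = 36,
                      lon_min = 68, lon_max = 98) {
  stopifnot(n_lat >= 1, n_lon >= 1, lat_max > lat_min, lon_max > lon_min,
            lat_min >= -90, lat_max <= 90)
  n_lat <- as.integer(n_lat); n_lon <- as.integer(n_lon)
  dlat <- (lat_max - lat_min) / n_lat
  dlon <- (lon_max - lon_min) / n_lon
  lat <- lat_min + (seq_len(n_lat) - 0.5) * dlat
  lon <- lon_min + (seq_len(n_lon) - 0.5) * dlon
  # area of a lat band slice: R^2 * dlon_rad * (sin(lat_hi) - sin(lat_lo))
  lat_lo <- (lat_min + (seq_len(n_lat) - 1) * dlat) * pi / 180
  lat_hi <- lat_lo + dlat * pi / 180
  area_row <- EARTH_RADIUS_KM^2 * (dlon * pi / 180) * (sin(lat_hi) - sin(lat_lo))
  structure(list(
    n_lat = n_lat, n_lon = n_lon,
    lat_min = lat_min, lat_max = lat_max,
    lon_min = lon_min, lon_max = lon_max,
    lat = lat, lon = lon, cell_area_row = area_row
  ), class = "grid_spec")
}

#' Matrix of cell areas (km^2) for a grid
#' @param spec A [grid_spec()].
#' @return `n_lat` x `n_lon` matrix of areas.
#' @export
cell_areas <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  matrix(rep(spec$cell_area_row, spec$n_lon), nrow = spec$n_lat)
}

#' Construct a gridded scalar field
#'
#' @param values Numeric `n_lat` x `n_lon` matrix (concentration in ug/m^3 or
#'   population counts), all finite, or a scalar recycled over the grid.
#' @param spec A [grid_spec()].
#' @param units Unit label carried for writers ("ug/m3" or "persons").
#' @return A `gridded_field`.
#' @export
gridded_field <- function(values, spec, units = "ug/m3") {
  stopifnot(inherits(spec, "grid_spec"))
  if (length(values) == 1L) {
    values <- matrix(as.numeric(values), spec$n_lat, spec$n_lon)
  }
  values <- as.matrix(values)
  if (!all(dim(values) == c(spec$n_lat, spec$n_lon))) {
    stop("field dimensions (", nrow(values), "x", ncol(values),
         ") do not match grid (", spec$n_lat, "x", spec$n_lon, ")")
  }
  if (!all(is.finite(values))) stop("field values must be finite")
  structure(list(values = values, spec = spec, units = units),
            class = "gridded_field")
}

#' @export
print.gridded_field <- function(x, ...) {
  cat(sprintf("<gridded_field %dx%d [%s] range %.3g..%.3g>\n",
              x$spec$n_lat, x$spec$n_lon, x$units,
              min(x$values), max(x$values)))
  invisible(x)
}

same_grid <- function(a, b) {
  sa <- a$spec; sb <- b$spec
  sa$n_lat == sb$n_lat && sa$n_lon == sb$n_lon &&
    isTRUE(all.equal(c(sa$lat_min, sa$lat_max, sa$lon_min, sa$lon_max),
                     c(sb$lat_min, sb$lat_max, sb$lon_min, sb$lon_max)))
}

check_same_grid <- function(a, b, what = "fields") {
  if (!same_grid(a, b)) stop("grid mismatch between ", what)
  invisible(TRUE)
}

#' Bundle a control concentration field with sector-off fields
#'
#' @param control `gridded_field` of the all-sources annual mean PM2.5.
#' @param sector_off Named list of `gridded_field`s, one per emission sector;
#'   names must be exactly AGR, BBU, DUS, ENE, IND, RES, TRA.
#' @return A `scenario_set`.
#' @export
scenario_set <- function(control, sector_off) {
  stopifnot(inherits(control, "gridded_field"))
  if (!setequal(names(sector_off), SECTOR_LABELS)) {
    stop("sector_off must contain exactly the sectors: ",
         paste(SECTOR_LABELS, collapse = ", "))
  }
  sector_off <- sector_off[SECTOR_LABELS]
  for (s in SECTOR_LABELS) check_same_grid(control, sector_off[[s]],
                                           paste("control and", s))
  structure(list(control = control, sector_off = sector_off),
            class = "scenario_set")
}

#' Emission sector labels
#'
#' Agriculture, open biomass burning, dust, power generation, industry,
#' residential energy use and land transport.
#' @export
SECTOR_LABELS <- c("AGR", "BBU", "DUS", "ENE", "IND", "RES", "TRA")

round_half_up <- function(x) floor(x + 0.5)
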