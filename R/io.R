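# Readers/writers for gridded fields, parameter ensembles and region masks.
#
# Gridded fields are stored as a self-describing text format: '#'-prefixed
# header lines carrying the grid definition, then a long-format CSV body
# (lat, lon[, week], value). Deterministic output: values printed with
# full precision so identical runs give byte-identical files.

field_header <- function(spec, units, n_week = NULL) {
  h <- c(
    sprintf("# pmburden gridded_field v1"),
    sprintf("# n_lat: %d", spec$n_lat),
    sprintf("# n_lon: %d", spec$n_lon),
    sprintf("# lat_min: %.10g", spec$lat_min),
    sprintf("# lat_max: %.10g", spec$lat_max),
    sprintf("# lon_min: %.10g", spec$lon_min),
    sprintf("# lon_max: %.10g", spec$lon_max),
    sprintf("# units: %s", units)
  )
  if (!is.null(n_week)) h <- c(h, sprintf("# n_week: %d", n_week))
  h
}

parse_header <- function(lines) {
  kv <- lines[grepl("^# [a-z_]+:", lines)]
  keys <- sub("^# ([a-z_]+):.*$", "\\1", kv)
  vals <- trimws(sub("^# [a-z_]+:", "", kv))
  stats::setNames(as.list(vals), keys)
}

#' Write a gridded field to a plain-text grid file
#'
#' @param field A [gridded_field()], or a list of 52 weekly fields sharing a
#'   grid (written with a `week` column).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  if (inherits(field, "gridded_field")) {
    spec <- field$spec
    df <- data.frame(
      lat = rep(spec$lat, times = spec$n_lon),
      lon = rep(spec$lon, each = spec$n_lat),
      value = as.vector(field$values)
    )
    hdr <- field_header(spec, field$units)
  } else {
    stopifnot(is.list(field), length(field) >= 1,
              all(vapply(field, inherits, TRUE, "gridded_field")))
    spec <- field[[1]]$spec
    nw <- length(field)
    df <- data.frame(
      week = rep(seq_len(nw), each = spec$n_lat * spec$n_lon),
      lat = rep(rep(spec$lat, times = spec$n_lon), nw),
      lon = rep(rep(spec$lon, each = spec$n_lat), nw),
      value = unlist(lapply(field, function(f) as.vector(f$values)),
                     use.names = FALSE)
    )
    hdr <- field_header(spec, field[[1]]$units, n_week = nw)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(df), collapse = ","), con)
  body <- do.call(paste, c(lapply(df, function(col) {
    if (is.numeric(col)) sprintf("%.12g", col) else as.character(col)
  }), sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Read a gridded field written by [write_field()]
#'
#' @param path File path.
#' @return A [gridded_field()], or a list of weekly fields if the file holds
#'   a weekly stack.
#' @export
read_field <- function(path) {
  lines <- readLines(path)
  hdr <- parse_header(lines[startsWith(lines, "#")])
  spec <- grid_spec(as.integer(hdr$n_lat), as.integer(hdr$n_lon),
                    as.numeric(hdr$lat_min), as.numeric(hdr$lat_max),
                    as.numeric(hdr$lon_min), as.numeric(hdr$lon_max))
  df <- utils::read.csv(textConnection(lines[!startsWith(lines, "#")]))
  if (!is.null(hdr$n_week)) {
    nw <- as.integer(hdr$n_week)
    lapply(seq_len(nw), function(w) {
      v <- df$value[df$week == w]
      gridded_field(matrix(v, spec$n_lat, spec$n_lon), spec, hdr$units)
    })
  } else {
    gridded_field(matrix(df$value, spec$n_lat, spec$n_lon), spec, hdr$units)
  }
}

#' Write an IER parameter ensemble to CSV
#'
#' Columns: disease, age_group, draw, alpha, beta, gamma, tmrel.
#' @param ens An `ier_ensemble` (see [gen_ier_parameters()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ier_csv <- function(ens, path) {
  stopifnot(inherits(ens, "ier_ensemble"))
  utils::write.csv(ens$draws, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an IER parameter ensemble from CSV
#'
#' Accepts any table with columns disease, age_group, draw, alpha, beta,
#' gamma, tmrel — e.g. a user-supplied parameter table — and validates the
#' ensemble contract (equal draw counts per stratum, positive parameters).
#' @param path CSV path.
#' @return An `ier_ensemble`.
#' @export
read_ier_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_ier_ensemble(df)
}

#' Read region masks from a GeoJSON FeatureCollection
#'
#' Each polygon feature is rasterised onto `spec` by cell-centre containment;
#' a cell claimed by several regions goes to the first-listed one.
#'
#' @param path GeoJSON file with Polygon/MultiPolygon features; the feature
#'   property `name` (or `NAME`) labels the region.
#' @param spec Target [grid_spec()].
#' @return Named list of logical `n_lat` x `n_lon` masks.
#' @export
read_region_masks <- function(path, spec) {
  gj <- jsonlite::read_json(path)
  stopifnot(identical(gj$type, "FeatureCollection"))
  masks <- list()
  claimed <- matrix(FALSE, spec$n_lat, spec$n_lon)
  for (feat in gj$features) {
    nm <- feat$properties$name
    if (is.null(nm)) nm <- feat$properties$NAME
    if (is.null(nm)) nm <- paste0("region_", length(masks) + 1L)
    geom <- feat$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type))
    m <- matrix(FALSE, spec$n_lat, spec$n_lon)
    for (poly in polys) {
      ring <- poly[[1]]  # outer ring; holes not supported
      px <- vapply(ring, function(p) as.numeric(p[[1]]), 0)
      py <- vapply(ring, function(p) as.numeric(p[[2]]), 0)
      for (i in seq_len(spec$n_lat)) for (j in seq_len(spec$n_lon)) {
        if (!m[i, j] && point_in_polygon(spec$lon[j], spec$lat[i], px, py))
          m[i, j] <- TRUE
      }
    }
    m <- m & !claimed
    claimed <- claimed | m
    masks[[nm]] <- m
  }
  masks
}

# Ray-casting point-in-polygon; boundary points count as inside.
point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((py[i] > y) != (py[j] > y))) {
      xint <- px[i] + (y - py[i]) / (py[j] - py[i]) * (px[j] - px[i])
      if (x < xint) inside <- !inside
      if (abs(x - xint) < 1e-12) return(TRUE)
    }
    j <- i
  }
  inside
}

#' Write rectangular region polygons as GeoJSON
#'
#' @param regions Named list of `c(lon_min, lat_min, lon_max, lat_max)` boxes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_geojson <- function(regions, path) {
  feats <- lapply(names(regions), function(nm) {
    b <- regions[[nm]]
    ring <- list(c(b[1], b[2]), c(b[3], b[2]), c(b[3], b[4]),
                 c(b[1], b[4]), c(b[1], b[2]))
    list(type = "Feature",
         properties = list(name = nm),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
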