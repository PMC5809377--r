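# Model-vs-observation evaluation statistics: normalised mean bias,
# Pearson correlation, ordinary-least-squares best-fit slope, and the
# sampling of gridded fields at site locations.

#' Paired model/observation series
#'
#' @param model,observed Numeric vectors of equal length (>= 2), finite.
#' @param season Season label: annual, DJF, MAM, JJA or SON.
#' @return A `paired_series`.
#' @export
paired_series <- function(model, observed, season = "annual") {
  stopifnot(length(model) == length(observed), length(model) >= 2,
            all(is.finite(model)), all(is.finite(observed)),
            season %in% c("annual", "DJF", "MAM", "JJA", "SON"))
  structure(list(model = as.numeric(model), observed = as.numeric(observed),
                 season = season), class = "paired_series")
}

#' Normalised mean bias
#'
#' `sum(model - observed) / sum(observed)`; zero for a perfect model and
#' invariant to a common rescaling of both series.
#'
#' @param p A [paired_series()].
#' @return Dimensionless NMB.
#' @export
nmb <- function(p) {
  stopifnot(inherits(p, "paired_series"))
  so <- sum(p$observed)
  if (so == 0) stop("sum of observations is zero; NMB undefined")
  sum(p$model - p$observed) / so
}

#' Pearson correlation between model and observations
#'
#' @param p A [paired_series()].
#' @return r in [-1, 1]; an error if either series is constant.
#' @export
pearson_r <- function(p) {
  stopifnot(inherits(p, "paired_series"))
  if (stats::sd(p$model) == 0 || stats::sd(p$observed) == 0) {
    stop("correlation undefined for a constant series")
  }
  stats::cor(p$model, p$observed)
}

#' Best-fit slope of model on observations
#'
#' Ordinary least squares of model values on observed values, with
#' intercept.
#'
#' @param p A [paired_series()].
#' @return The OLS slope.
#' @export
best_fit_slope <- function(p) {
  stopifnot(inherits(p, "paired_series"))
  if (stats::var(p$observed) == 0) {
    stop("slope undefined for constant observations")
  }
  unname(stats::coef(stats::lm(p$model ~ p$observed))[2])
}

# sample one location from a field; nearest cell or bilinear in cell-centre
# space (edges clamp to the boundary cell centres)
sample_field <- function(field, lat, lon, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  spec <- field$spec
  if (lat < spec$lat_min || lat > spec$lat_max ||
      lon < spec$lon_min || lon > spec$lon_max) {
    stop("site (", lat, ", ", lon, ") lies outside the grid")
  }
  if (method == "nearest") {
    i <- which.min(abs(spec$lat - lat))
    j <- which.min(abs(spec$lon - lon))
    return(field$values[i, j])
  }
  fi <- (lat - spec$lat[1]) / (spec$lat[2] - spec$lat[1]) + 1
  fj <- (lon - spec$lon[1]) / (spec$lon[2] - spec$lon[1]) + 1
  fi <- min(max(fi, 1), spec$n_lat)
  fj <- min(max(fj, 1), spec$n_lon)
  i0 <- floor(fi); j0 <- floor(fj)
  i1 <- min(i0 + 1, spec$n_lat); j1 <- min(j0 + 1, spec$n_lon)
  wi <- fi - i0; wj <- fj - j0
  (1 - wi) * (1 - wj) * field$values[i0, j0] +
    (1 - wi) * wj * field$values[i0, j1] +
    wi * (1 - wj) * field$values[i1, j0] +
    wi * wj * field$values[i1, j1]
}

#' Pair a gridded field with site observations
#'
#' Samples the field at each site location and pairs the sampled values
#' with the observed ones for a season.
#'
#' @param field A [gridded_field()].
#' @param sites Site table (lat, lon, season, value) as from
#'   [gen_observation_sites()] or a CSV of the same shape.
#' @param season Season to select from `sites`.
#' @param method `"bilinear"` or `"nearest"` sampling.
#' @return A [paired_series()].
#' @export
sample_at_sites <- function(field, sites, season = "annual",
                            method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  s <- sites[sites$season == season, ]
  if (nrow(s) < 2) stop("need at least 2 sites for season ", season)
  model <- vapply(seq_len(nrow(s)), function(i) {
    sample_field(field, s$lat[i], s$lon[i], method)
  }, 0)
  paired_series(model, s$value, season)
}

#' Evaluation metrics table across seasons
#'
#' @param field A [gridded_field()].
#' @param sites Site table with a `season` column.
#' @param method Sampling method.
#' @return Data frame (season, n, nmb, r, slope).
#' @export
evaluate_field <- function(field, sites, method = "bilinear") {
  seasons <- intersect(c("annual", "DJF", "MAM", "JJA", "SON"),
                       unique(sites$season))
  rows <- lapply(seasons, function(se) {
    p <- sample_at_sites(field, sites, se, method)
    data.frame(season = se, n = length(p$model), nmb = nmb(p),
               r = pearson_r(p), slope = best_fit_slope(p))
  })
  do.call(rbind, rows)
}
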