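# 95% uncertainty intervals by combining component fractional errors in
# quadrature (square root of the sum of squares). Components: population
# (+/-2%), concentration (+/-2 SD of weekly values about the annual mean),
# exposure-response (ensemble percentiles of the attributable fraction),
# and baseline mortality (table bounds). Low and high sides are combined
# separately, so intervals may be asymmetric.

#' Combine fractional errors in quadrature
#'
#' @param fracs Non-negative fractional errors (dimensionless).
#' @return `sqrt(sum(fracs^2))`; at least `max(fracs)`, and equal to the
#'   single element for a length-1 input.
#' @export
quadrature <- function(fracs) {
  if (length(fracs) == 0) return(0)
  if (any(fracs < 0)) stop("fractional errors must be >= 0")
  sqrt(sum(fracs^2))
}

#' Concentration fractional error from weekly variability
#'
#' Per cell, the 95% bound on the annual mean is taken as +/- 2 sample
#' standard deviations of the 52 weekly concentrations; the per-cell
#' fractional error `2*SD/mean` is then population-weighted into a single
#' national fraction. Cells with zero annual mean (or zero population) are
#' excluded.
#'
#' @param weekly List of weekly [gridded_field()]s.
#' @param pop Population [gridded_field()] on the same grid.
#' @param per_cell If `TRUE`, return the per-cell table instead of the
#'   national fraction.
#' @return Single non-negative fraction (applies to both sides), or with
#'   `per_cell = TRUE` a data frame (cell, mean, pop, frac) over the cells
#'   with positive mean concentration and population.
#' @export
pm25_fractional_error <- function(weekly, pop, per_cell = FALSE) {
  stopifnot(is.list(weekly), length(weekly) >= 2)
  for (w in weekly) check_same_grid(w, pop, "weekly field and population")
  wk <- vapply(weekly, function(f) as.vector(f$values),
               numeric(length(pop$values)))
  m <- rowMeans(wk)
  sdw <- apply(wk, 1, stats::sd)
  p <- as.vector(pop$values)
  keep <- m > 0 & p > 0
  if (!any(keep)) stop("no cells with positive mean concentration and population")
  frac_cell <- 2 * sdw[keep] / m[keep]
  if (per_cell) {
    return(data.frame(cell = which(keep), mean = m[keep], pop = p[keep],
                      frac = frac_cell))
  }
  sum(frac_cell * p[keep]) / sum(p[keep])
}

#' Propagate a concentration fractional error through the IER
#'
#' Concentration bounds `c*(1-f)` and `c*(1+f)` are mapped to burden-scale
#' fractional errors via the ensemble-mean attributable fraction
#' (RR-1)/RR, so that where the exposure-response curve saturates a large
#' concentration error translates into a much smaller burden error.
#'
#' Vectorised over cells: with per-cell concentrations, per-cell fractional
#' errors and population weights, each cell's bounds pass through the curve
#' where that cell actually sits, and the resulting per-cell burden-scale
#' fractions are combined with burden-proportional weights (population x
#' attributable fraction). Saturated high-burden cells then contribute
#' small fractional errors, as they should.
#'
#' @param ens An `ier_ensemble`.
#' @param c Representative concentration(s) (ug/m3, > 0); scalar or
#'   per-cell vector.
#' @param frac Per-side concentration fractional error(s), recycled
#'   against `c` (e.g. from [pm25_fractional_error()]).
#' @param diseases Diseases to include.
#' @param weights Optional named burden-share weights per disease.
#' @param pop Optional population weights matching `c` (defaults to equal).
#' @return `c(low, high)` burden-scale fractional errors.
#' @export
propagate_conc_error <- function(ens, c, frac, diseases = DISEASES,
                                 weights = NULL, pop = NULL) {
  stopifnot(all(c >= 0), all(frac >= 0))
  frac <- rep_len(frac, length(c))
  if (is.null(pop)) pop <- rep(1, length(c))
  mean_af <- function(cc, d) {
    dd <- ens$draws
    a <- if (any(dd$disease == d & dd$age_group == "all")) "all"
         else dd$age_group[dd$disease == d][1]
    rr <- rr_mean_vector(cc, ensemble_draws(ens, d, a))
    (rr - 1) / rr
  }
  per <- vapply(diseases, function(d) {
    af0 <- mean_af(c, d)
    keep <- af0 > 0 & pop > 0
    if (!any(keep)) return(c(0, 0))
    af_lo <- mean_af(pmax(c * (1 - frac), 0), d)
    af_hi <- mean_af(c * (1 + frac), d)
    w <- pop[keep] * af0[keep]          # ~ burden carried by each cell
    w <- w / sum(w)
    c(sum(w * (af0[keep] - af_lo[keep]) / af0[keep]),
      sum(w * (af_hi[keep] - af0[keep]) / af0[keep]))
  }, numeric(2))
  if (is.null(weights)) weights <- rep(1, length(diseases))
  w <- weights / sum(weights)
  c(low = sum(per[1, ] * w), high = sum(per[2, ] * w))
}

#' Exposure-response fractional errors from the ensemble
#'
#' Fractional errors of the attributable fraction (RR-1)/RR at a
#' representative concentration (typically the national population-weighted
#' mean), from the empirical 2.5th/97.5th percentiles of the draws. One
#' (low, high) pair per disease, combined across diseases by
#' burden-share weights when given.
#'
#' @param ens An `ier_ensemble`.
#' @param c Representative concentration (ug/m3).
#' @param diseases Diseases to include.
#' @param age_group Age group used for age-resolved strata.
#' @param weights Optional named burden-share weights per disease.
#' @return `c(low, high)` fractional errors.
#' @export
rr_fractional_error <- function(ens, c, diseases = DISEASES,
                                age_group = "all", weights = NULL) {
  per <- vapply(diseases, function(d) {
    a <- age_group
    dd <- ens$draws
    if (!any(dd$disease == d & dd$age_group == a)) a <- "all"
    if (!any(dd$disease == d & dd$age_group == a)) {
      a <- dd$age_group[dd$disease == d][1]
    }
    draws <- ensemble_draws(ens, d, a)
    rr <- relative_risk(c, draws$alpha, draws$beta, draws$gamma, draws$tmrel)
    af <- (rr - 1) / rr
    m <- mean(af)
    if (m <= 0) return(c(0, 0))
    c((m - sorted_percentile(af, 0.025)) / m,
      (sorted_percentile(af, 0.975) - m) / m)
  }, numeric(2))
  if (is.null(weights)) weights <- rep(1, length(diseases))
  w <- weights / sum(weights)
  c(low = sum(per[1, ] * w), high = sum(per[2, ] * w))
}

#' Baseline-mortality fractional errors from table bounds
#'
#' @param bm A `baseline_mortality` table.
#' @param weights Optional named burden-share weights per disease.
#' @return `c(low, high)` fractional errors, rate-weighted within disease
#'   and weight-averaged across diseases.
#' @export
baseline_fractional_error <- function(bm, weights = NULL) {
  ds <- unique(bm$disease)
  per <- vapply(ds, function(d) {
    b <- bm[bm$disease == d & bm$mean > 0, ]
    if (nrow(b) == 0) return(c(0, 0))
    w <- b$mean / sum(b$mean)
    c(sum(w * (b$mean - b$lower) / b$mean),
      sum(w * (b$upper - b$mean) / b$mean))
  }, numeric(2))
  if (is.null(weights)) weights <- rep(1, length(ds))
  w <- weights / sum(weights)
  c(low = sum(per[1, ] * w), high = sum(per[2, ] * w))
}

#' Attach a quadrature 95% interval to a mean burden
#'
#' @param mean_burden Central estimate (> 0).
#' @param components List of per-component fractional errors; each element
#'   either a single fraction (symmetric) or `c(low, high)`.
#' @return An `uncertain_quantity`: list(mean, lower_95, upper_95,
#'   fractional_error_low, fractional_error_high).
#' @export
combine_burden_ui <- function(mean_burden, components) {
  lows <- vapply(components, function(f) f[[1]], 0)
  highs <- vapply(components, function(f) if (length(f) > 1) f[[2]] else f[[1]], 0)
  flo <- quadrature(lows)
  fhi <- quadrature(highs)
  structure(list(mean = mean_burden,
                 lower_95 = mean_burden * (1 - flo),
                 upper_95 = mean_burden * (1 + fhi),
                 fractional_error_low = flo,
                 fractional_error_high = fhi),
            class = "uncertain_quantity")
}

#' @export
print.uncertain_quantity <- function(x, ...) {
  cat(sprintf("%.4g (95UI: %.4g-%.4g)\n", x$mean, x$lower_95, x$upper_95))
  invisible(x)
}
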