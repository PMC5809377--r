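# Exposure metrics on gridded fields: population weighting, sector
# reductions, threshold exceedance, block coarsening and concentration
# capping.

#' Population-weighted mean concentration
#'
#' `sum(c * P) / sum(P)` over grid cells. Cells with zero population
#' contribute nothing; the result lies within the concentration range of
#' the populated cells.
#'
#' @param conc Concentration [gridded_field()] (ug/m3).
#' @param pop Population [gridded_field()] on the same grid (persons).
#' @return Population-weighted mean (ug/m3).
#' @export
population_weighted_mean <- function(conc, pop) {
  check_same_grid(conc, pop, "concentration and population")
  P <- pop$values
  if (any(P < 0)) stop("population must be >= 0")
  tot <- sum(P)
  if (tot <= 0) stop("total population is zero; population-weighted mean undefined")
  sum(conc$values * P) / tot
}

#' Sector contribution to population-weighted PM2.5
#'
#' Absolute and fractional reduction in population-weighted annual-mean
#' PM2.5 caused by removing one emission sector.
#'
#' @param scen A [scenario_set()].
#' @param pop Population [gridded_field()].
#' @param sector One of [SECTOR_LABELS].
#' @return List with `absolute` (ug/m3), `fraction` (of the control
#'   population-weighted mean) and `percent` (half-up integer rounding).
#' @export
sector_reduction <- function(scen, pop, sector) {
  stopifnot(inherits(scen, "scenario_set"), sector %in% names(scen$sector_off))
  pwm_all <- population_weighted_mean(scen$control, pop)
  pwm_off <- population_weighted_mean(scen$sector_off[[sector]], pop)
  absolute <- pwm_all - pwm_off
  fraction <- absolute / pwm_all
  list(absolute = absolute, fraction = fraction,
       percent = round_half_up(100 * fraction))
}

#' Fraction of the population above a concentration threshold
#'
#' @param conc Concentration [gridded_field()].
#' @param pop Population [gridded_field()] on the same grid.
#' @param threshold Concentration threshold (ug/m3); cells with
#'   concentration strictly above it count as exceeding.
#' @return Population fraction in (0, 1]; non-increasing in `threshold`.
#' @export
exceedance_fraction <- function(conc, pop, threshold) {
  check_same_grid(conc, pop, "concentration and population")
  tot <- sum(pop$values)
  if (tot <= 0) stop("total population is zero")
  sum(pop$values[conc$values > threshold]) / tot
}

#' Coarsen a field by an integer block factor
#'
#' Concentration mode averages each `factor` x `factor` block with
#' cell-area weights; population mode sums the block (total conserved
#' exactly). When `factor` does not divide a dimension the trailing partial
#' blocks simply contain fewer cells.
#'
#' @param field A [gridded_field()].
#' @param factor Positive integer block size.
#' @param mode `"concentration"` (area-weighted mean) or `"population"`
#'   (sum).
#' @return A [gridded_field()] on the coarse grid.
#' @export
coarsen <- function(field, factor, mode = c("concentration", "population")) {
  mode <- match.arg(mode)
  stopifnot(inherits(field, "gridded_field"), factor >= 1,
            factor == round(factor))
  factor <- as.integer(factor)
  spec <- field$spec
  ni <- ceiling(spec$n_lat / factor)
  nj <- ceiling(spec$n_lon / factor)
  cspec <- grid_spec(ni, nj, spec$lat_min, spec$lat_max,
                     spec$lon_min, spec$lon_max)
  area <- cell_areas(spec)
  out <- matrix(0, ni, nj)
  bi <- ceiling(seq_len(spec$n_lat) / factor)
  bj <- ceiling(seq_len(spec$n_lon) / factor)
  for (i in seq_len(ni)) {
    ri <- which(bi == i)
    for (j in seq_len(nj)) {
      rj <- which(bj == j)
      v <- field$values[ri, rj, drop = FALSE]
      if (mode == "population") {
        out[i, j] <- sum(v)
      } else {
        a <- area[ri, rj, drop = FALSE]
        out[i, j] <- sum(v * a) / sum(a)
      }
    }
  }
  gridded_field(out, cspec, field$units)
}

#' Cap concentrations at a ceiling
#'
#' Cell-wise `min(c, cap)`; idempotent sensitivity transform for capping
#' annual-mean concentrations at e.g. 80 or 50 ug/m3.
#'
#' @param field Concentration [gridded_field()].
#' @param cap Ceiling (ug/m3, >= 0).
#' @return A [gridded_field()] with no value above `cap`.
#' @export
cap_concentrations <- function(field, cap) {
  stopifnot(inherits(field, "gridded_field"), cap >= 0)
  gridded_field(pmin(field$values, cap), field$spec, field$units)
}

#' Exposure summary across a scenario set
#'
#' @param scen A [scenario_set()].
#' @param pop Population [gridded_field()].
#' @return Data frame (scenario, pwm, reduction, fraction, percent) with the
#'   control row first.
#' @export
exposure_summary <- function(scen, pop) {
  pwm_all <- population_weighted_mean(scen$control, pop)
  rows <- lapply(names(scen$sector_off), function(s) {
    r <- sector_reduction(scen, pop, s)
    data.frame(scenario = s,
               pwm = pwm_all - r$absolute,
               reduction = r$absolute,
               fraction = r$fraction,
               percent = r$percent)
  })
  rbind(data.frame(scenario = "control", pwm = pwm_all, reduction = 0,
                   fraction = 0, percent = 0),
        do.call(rbind, rows))
}
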