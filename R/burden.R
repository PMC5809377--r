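# Premature mortality and years of life lost from concentration fields.
#
# Per cell i and disease j:  M_ij = P_i * I_j * (RR_jc - 1) / RR_jc,
# with the population split across age groups by a national age structure,
# ALRI applied to all ages and IHD/CEV/COPD/LC to adults (>= 25 y).
# YLL_ij = M_ij * LE(age at death).

#' Attributable mortality in one stratum
#'
#' @param P Population at risk (persons, >= 0).
#' @param I Baseline mortality rate (deaths per person-year, >= 0).
#' @param RR Relative risk (>= 1).
#' @return Deaths per year: `P * I * (RR - 1) / RR`, zero when `RR = 1` and
#'   always below `P * I`.
#' @export
mortality_cell <- function(P, I, RR) {
  if (any(P < 0) || any(I < 0)) stop("P and I must be >= 0")
  if (any(RR < 1)) stop("RR must be >= 1 (IER contract)")
  P * I * (RR - 1) / RR
}

#' Classify grid cells as urban by population density
#'
#' @param pop Population [gridded_field()] (persons per cell).
#' @param threshold Density threshold, persons per km^2; cells at or above
#'   it are urban. Default 400.
#' @return Logical `n_lat` x `n_lon` matrix (TRUE = urban).
#' @export
classify_urban <- function(pop, threshold = 400) {
  stopifnot(inherits(pop, "gridded_field"))
  pop$values / cell_areas(pop$spec) >= threshold
}

#' Scale baseline mortality rates by regional ratios
#'
#' Applies region-to-nation rate ratios to the causes whose baseline rates
#' track regional socioeconomic conditions (COPD, IHD, CEV); ALRI and LC
#' keep the national rates. Mean, lower and upper bounds are scaled alike.
#'
#' @param bm A `baseline_mortality` table.
#' @param ratios Named numeric vector of ratios, one per region.
#' @param region Region whose ratio to apply.
#' @return A scaled `baseline_mortality` table.
#' @export
apply_state_scaling <- function(bm, ratios, region) {
  stopifnot(inherits(bm, "baseline_mortality"), region %in% names(ratios))
  r <- ratios[[region]]
  if (r < 0) stop("scaling ratio must be >= 0")
  scaled <- bm$disease %in% c("COPD", "IHD", "CEV")
  for (col in c("mean", "lower", "upper")) {
    bm[[col]][scaled] <- bm[[col]][scaled] * r
  }
  bm
}

# ages a disease applies to
applicable_ages <- function(disease, age_groups) {
  if (disease == "ALRI") age_groups
  else age_groups[age_group_lower(age_groups) >= 25]
}

#' Compute the burden table for a concentration field
#'
#' Evaluates the mean ensemble relative risk at each cell's annual-mean
#' concentration for every (disease, age) stratum, converts it to
#' attributable mortality and years of life lost, and aggregates over
#' region masks and the urban/rural split.
#'
#' @param conc Annual-mean concentration [gridded_field()].
#' @param pop Population [gridded_field()] on the same grid.
#' @param ages An `age_structure` (national fractions per age group).
#' @param bm A `baseline_mortality` table covering the diseases and ages.
#' @param ens An `ier_ensemble`.
#' @param lt A `life_table`.
#' @param masks Optional named list of logical region masks partitioning the
#'   grid; `NULL` treats the whole grid as one region `"all"`. Region
#'   scaling ratios (see [apply_state_scaling()]) may be given via
#'   `state_ratios`.
#' @param diseases Diseases to include.
#' @param urban_threshold Urban density threshold (persons/km^2).
#' @param state_ratios Optional named ratios applied to COPD/IHD/CEV rates
#'   per region.
#' @return A `burden_table` data frame (region, class, disease, age_group,
#'   population, mortality, yll).
#' @export
compute_burden <- function(conc, pop, ages, bm, ens, lt, masks = NULL,
                           diseases = unique(bm$disease),
                           urban_threshold = 400, state_ratios = NULL) {
  check_same_grid(conc, pop, "concentration and population")
  stopifnot(inherits(ages, "age_structure"),
            inherits(bm, "baseline_mortality"),
            inherits(ens, "ier_ensemble"),
            inherits(lt, "life_table"))
  if (is.null(masks)) {
    masks <- list(all = matrix(TRUE, conc$spec$n_lat, conc$spec$n_lon))
  }
  urban <- classify_urban(pop, urban_threshold)
  cvec <- as.vector(conc$values)
  pvec <- as.vector(pop$values)
  le <- stats::setNames(lt$le, lt$age_group)
  frac <- stats::setNames(ages$fraction, ages$age_group)

  rows <- list()
  for (d in diseases) {
    for (a in applicable_ages(d, ages$age_group)) {
      rate_row <- bm[bm$disease == d & bm$age_group == a, ]
      if (nrow(rate_row) == 0 || rate_row$mean == 0) next
      draws <- ensemble_draws(ens, d, a)
      rrm <- rr_mean_vector(cvec, draws)
      for (rg in names(masks)) {
        I <- rate_row$mean
        if (!is.null(state_ratios) && rg %in% names(state_ratios) &&
            d %in% c("COPD", "IHD", "CEV")) {
          I <- I * state_ratios[[rg]]
        }
        mvec <- as.vector(masks[[rg]])
        for (cl in c("urban", "rural")) {
          sel <- mvec & (as.vector(urban) == (cl == "urban"))
          if (!any(sel)) next
          Psel <- pvec[sel] * frac[[a]]
          M <- sum(mortality_cell(Psel, I, rrm[sel]))
          rows[[length(rows) + 1L]] <- data.frame(
            region = rg, class = cl, disease = d, age_group = a,
            population = sum(Psel), mortality = M, yll = M * le[[a]])
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(region = character(), class = character(),
                      disease = character(), age_group = character(),
                      population = numeric(), mortality = numeric(),
                      yll = numeric())
  }
  rownames(out) <- NULL
  class(out) <- c("burden_table", "data.frame")
  out
}

#' Total mortality and YLL of a burden table
#'
#' @param bt A `burden_table`.
#' @param by Optional grouping column(s) (`"disease"`, `"region"`,
#'   `"class"`, `"age_group"`); `NULL` gives the grand total.
#' @return Data frame with `mortality` and `yll` totals.
#' @export
burden_total <- function(bt, by = NULL) {
  if (is.null(by)) {
    return(data.frame(mortality = sum(bt$mortality), yll = sum(bt$yll)))
  }
  agg <- stats::aggregate(bt[c("mortality", "yll")], by = bt[by], FUN = sum)
  agg[do.call(order, agg[by]), , drop = FALSE]
}

#' Recompute YLL from mortality with a different life table
#'
#' YLL scales linearly with the life expectancy remaining at the age of
#' death, so swapping the reference life table rescales each stratum.
#'
#' @param bt A `burden_table`.
#' @param lt A `life_table` covering the table's age groups.
#' @return The `burden_table` with its `yll` column replaced.
#' @export
yll_from_mortality <- function(bt, lt) {
  stopifnot(inherits(lt, "life_table"))
  le <- stats::setNames(lt$le, lt$age_group)
  if (!all(bt$age_group %in% names(le))) {
    stop("life table does not cover all age groups in the burden table")
  }
  bt$yll <- bt$mortality * le[bt$age_group]
  bt
}

#' Gridded mortality field for mapping
#'
#' Per-cell total attributable mortality summed over diseases and ages
#' (means only), on the grid of `conc`.
#'
#' @inheritParams compute_burden
#' @return A [gridded_field()] of deaths per year per cell.
#' @export
mortality_field <- function(conc, pop, ages, bm, ens,
                            diseases = unique(bm$disease)) {
  check_same_grid(conc, pop, "concentration and population")
  cvec <- as.vector(conc$values)
  pvec <- as.vector(pop$values)
  frac <- stats::setNames(ages$fraction, ages$age_group)
  total <- numeric(length(cvec))
  for (d in diseases) {
    for (a in applicable_ages(d, ages$age_group)) {
      rate_row <- bm[bm$disease == d & bm$age_group == a, ]
      if (nrow(rate_row) == 0 || rate_row$mean == 0) next
      rrm <- rr_mean_vector(cvec, ensemble_draws(ens, d, a))
      total <- total + mortality_cell(pvec * frac[[a]], rate_row$mean, rrm)
    }
  }
  gridded_field(matrix(total, conc$spec$n_lat, conc$spec$n_lon),
                conc$spec, "deaths/yr")
}
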