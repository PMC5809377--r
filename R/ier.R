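# Integrated exposure-response (IER) relative-risk model.
#
# RR(c) = 1                                       for c <= tmrel
#         1 + alpha * (1 - exp(-beta*(c-tmrel)^gamma))  otherwise
#
# alpha is the maximum excess risk (saturation level), beta the rate, gamma
# the shape, and tmrel the counterfactual concentration below which no
# excess risk is assigned.

#' IER relative risk at a concentration
#'
#' @param c Annual-mean PM2.5 concentration(s), ug/m3, >= 0. Vectorised.
#' @param alpha,beta,gamma Positive IER parameters (scalars or vectors
#'   recycled against `c`).
#' @param tmrel Counterfactual threshold (ug/m3).
#' @return Relative risk, >= 1; exactly 1 at and below `tmrel`, saturating
#'   at `1 + alpha` as `c` grows.
#' @export
relative_risk <- function(c, alpha, beta, gamma, tmrel) {
  if (any(c < 0)) stop("concentration must be >= 0")
  if (any(alpha <= 0) || any(beta <= 0) || any(gamma <= 0)) {
    stop("alpha, beta and gamma must be positive")
  }
  excess <- pmax(c - tmrel, 0)
  1 + alpha * (1 - exp(-beta * excess^gamma)) * (excess > 0)
}

# type-7 (sorted-array linear interpolation) percentile, written out so the
# ensemble summary does not depend on stats::quantile defaults
sorted_percentile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

#' Ensemble relative risk with 95% uncertainty interval
#'
#' Evaluates the IER at `c` for every parameter draw of the stratum and
#' summarises the draws by their mean and empirical 2.5th/97.5th
#' percentiles.
#'
#' @param c Concentration (ug/m3, scalar >= 0).
#' @param ens An `ier_ensemble`.
#' @param disease Disease label.
#' @param age_group Age-group label (falls back to the shared `"all"`
#'   stratum for diseases without age-specific parameters).
#' @return List with `mean`, `lower_95`, `upper_95` (all >= 1, ordered).
#' @export
rr_ensemble <- function(c, ens, disease, age_group = "all") {
  stopifnot(inherits(ens, "ier_ensemble"), length(c) == 1)
  d <- ensemble_draws(ens, disease, age_group)
  rr <- relative_risk(c, d$alpha, d$beta, d$gamma, d$tmrel)
  list(mean = mean(rr),
       lower_95 = sorted_percentile(rr, 0.025),
       upper_95 = sorted_percentile(rr, 0.975))
}

#' Mean/95UI relative-risk curve over a concentration grid
#'
#' @param ens An `ier_ensemble`.
#' @param disease,age_group Stratum selector.
#' @param c_grid Concentrations (ug/m3), any order.
#' @return Data frame (c, mean, lower_95, upper_95).
#' @export
rr_curve <- function(ens, disease, age_group = "all",
                     c_grid = seq(0, 300, by = 5)) {
  rows <- lapply(c_grid, function(cc) {
    r <- rr_ensemble(cc, ens, disease, age_group)
    data.frame(c = cc, mean = r$mean,
               lower_95 = r$lower_95, upper_95 = r$upper_95)
  })
  do.call(rbind, rows)
}

# Mean-over-draws RR for a vector of concentrations (one stratum).
# Used by the burden engine; exact (no interpolation), vectorised over
# cells x draws.
rr_mean_vector <- function(conc, draws) {
  n <- length(conc)
  out <- numeric(n)
  # loop over draws, accumulate; memory stays O(cells)
  for (k in seq_len(nrow(draws))) {
    excess <- pmax(conc - draws$tmrel[k], 0)
    out <- out + 1 + draws$alpha[k] *
      (1 - exp(-draws$beta[k] * excess^draws$gamma[k])) * (excess > 0)
  }
  out / nrow(draws)
}
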