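# Synthetic inputs emulating the statistical structure of the real study
# data: spatially correlated PM2.5 with a high-concentration band, dense
# urban population cells, weekly variability around the annual mean,
# sector-off fields as fractional reductions of the control, right-skewed
# IER parameter ensembles, baseline mortality tables and a reference life
# table. These are stand-ins with the right structure for testing the
# pipeline offline; none of them are the licensed GBD/GPW/CPCB datasets.

#' Diseases with quantified PM2.5 burden
#'
#' Acute lower respiratory infection (ALRI, all ages), ischaemic heart
#' disease (IHD), cerebrovascular disease (CEV), chronic obstructive
#' pulmonary disease (COPD) and lung cancer (LC), the latter four for adults
#' aged 25 and over.
#' @export
DISEASES <- c("ALRI", "IHD", "CEV", "COPD", "LC")

#' Standard age groups
#'
#' Early/late/post-neonatal (EN/LN/PN), then 5-year bands from 1-4 up to 80+.
#' @export
AGE_GROUPS <- c("EN", "LN", "PN", "1-4",
                paste(seq(5, 75, 5), seq(9, 79, 5), sep = "-"), "80+")

#' Lower bound (years) of an age group label
#' @param groups Character vector of age-group labels.
#' @return Numeric lower bounds (neonatal groups are 0).
#' @export
age_group_lower <- function(groups) {
  vapply(groups, function(g) {
    if (g %in% c("EN", "LN", "PN")) return(0)
    as.numeric(sub("^([0-9]+).*$", "\\1", g))
  }, 0, USE.NAMES = FALSE)
}

# midpoint age used for life-expectancy lookup
age_group_mid <- function(groups) {
  low <- age_group_lower(groups)
  ifelse(groups == "80+", 84,
         ifelse(groups %in% c("EN", "LN", "PN"), 0,
                ifelse(groups == "1-4", 2.5, low + 2.5)))
}

#' Adult age groups (25 years and over)
#' @export
ADULT_AGE_GROUPS <- AGE_GROUPS[age_group_lower(AGE_GROUPS) >= 25]

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the study conditions the pipeline assumes: a pollution
#' band peaking above 100 ug/m3 over a low background, smooth spatial
#' correlation, moderate week-to-week variability, and sector shares close
#' to the population-weighted contributions of the seven emission sectors
#' (residential energy use dominant at ~50%).
#'
#' @param seed Integer RNG seed.
#' @param pollution_band_amplitude Peak amplitude of the high-PM2.5 band
#'   (ug/m3) added over the background.
#' @param background_level Spatially uniform background PM2.5 (ug/m3).
#' @param spatial_correlation_length Gaussian smoothing kernel width, in
#'   cells, for all correlated noise fields.
#' @param weekly_cv Coefficient of variation of weekly concentrations about
#'   the annual mean (dimensionless, >= 0).
#' @param sector_fractions Named mean fractional PM2.5 contribution per
#'   sector, each in [0,1], summing to at most 1.
#' @param urban_fraction Fraction of cells seeded as dense urban cores.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 42L,
                             pollution_band_amplitude = 130,
                             background_level = 15,
                             spatial_correlation_length = 3,
                             weekly_cv = 0.35,
                             sector_fractions = c(AGR = 0.003, BBU = 0.028,
                                                  DUS = 0.0002, ENE = 0.205,
                                                  IND = 0.16, RES = 0.50,
                                                  TRA = 0.10),
                             urban_fraction = 0.12) {
  if (pollution_band_amplitude < 0) stop("pollution_band_amplitude must be >= 0")
  if (background_level < 0) stop("background_level must be >= 0")
  if (weekly_cv < 0) stop("weekly_cv must be >= 0")
  if (spatial_correlation_length < 0) stop("spatial_correlation_length must be >= 0")
  if (any(sector_fractions < 0 | sector_fractions > 1)) {
    stop("every sector fraction must lie in [0, 1]")
  }
  if (sum(sector_fractions) > 1 + 1e-12) {
    stop("sector_fractions must sum to at most 1")
  }
  if (urban_fraction < 0 || urban_fraction > 1) stop("urban_fraction in [0,1]")
  structure(list(seed = as.integer(seed),
                 pollution_band_amplitude = pollution_band_amplitude,
                 background_level = background_level,
                 spatial_correlation_length = spatial_correlation_length,
                 weekly_cv = weekly_cv,
                 sector_fractions = sector_fractions,
                 urban_fraction = urban_fraction),
            class = "synthetic_config")
}

# Gaussian zonal band profile over latitude, centred in the upper third of
# the domain (the heavily polluted, densely settled plain).
band_profile <- function(spec) {
  centre <- spec$lat_min + 0.70 * (spec$lat_max - spec$lat_min)
  width <- 0.12 * (spec$lat_max - spec$lat_min)
  exp(-0.5 * ((spec$lat - centre) / width)^2)
}

# Separable Gaussian smoothing with truncated, renormalised kernels: keeps
# the mean approximately and needs no padding assumptions at the edges.
smooth_gaussian <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  smooth_1d <- function(x) {
    n <- length(x)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - r); hi <- min(n, i + r)
      w <- k[(lo - i + r + 1L):(hi - i + r + 1L)]
      out[i] <- sum(x[lo:hi] * w) / sum(w)
    }
    out
  }
  m <- matrix(apply(m, 2, smooth_1d), nrow(m), ncol(m))
  t(matrix(apply(m, 1, smooth_1d), ncol(m), nrow(m)))
}

# correlated noise field, recentred to mean 0 and rescaled to unit variance
correlated_noise <- function(spec, sigma) {
  z <- matrix(stats::rnorm(spec$n_lat * spec$n_lon), spec$n_lat, spec$n_lon)
  s <- smooth_gaussian(z, sigma)
  sd_s <- stats::sd(s)
  if (is.finite(sd_s) && sd_s > 0) s <- (s - mean(s)) / sd_s else s[] <- 0
  s
}

#' Generate the control PM2.5 field with its weekly series
#'
#' The annual mean is a uniform background plus a zonal high-concentration
#' band (log-normally modulated, spatially correlated), mimicking a heavily
#' polluted plain in the north of the domain. The 52 weekly fields are the
#' annual mean times log-normal multiplicative noise with the configured
#' coefficient of variation, renormalised cell-wise so the weekly mean
#' equals the annual mean exactly.
#'
#' @param spec A [grid_spec()].
#' @param cfg A [synthetic_config()].
#' @return List with `annual` (a [gridded_field()]) and `weekly` (list of 52
#'   fields on the same grid).
#' @export
gen_pm25_control <- function(spec, cfg) {
  stopifnot(inherits(spec, "grid_spec"), inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  band <- matrix(rep(band_profile(spec), spec$n_lon), spec$n_lat, spec$n_lon)
  g <- correlated_noise(spec, cfg$spatial_correlation_length)
  sdlog <- 0.15
  modulation <- exp(sdlog * g - sdlog^2 / 2)
  annual_vals <- cfg$background_level +
    cfg$pollution_band_amplitude * band * modulation
  annual <- gridded_field(annual_vals, spec, "ug/m3")

  weekly <- vector("list", 52L)
  if (cfg$weekly_cv == 0) {
    for (w in seq_len(52L)) weekly[[w]] <- annual
  } else {
    sl <- sqrt(log(1 + cfg$weekly_cv^2))
    eps <- matrix(exp(stats::rnorm(52L * spec$n_lat * spec$n_lon,
                                   -sl^2 / 2, sl)),
                  nrow = 52L)
    eps <- sweep(eps, 2, colMeans(eps), "/")  # exact weekly/annual closure
    for (w in seq_len(52L)) {
      weekly[[w]] <- gridded_field(
        annual_vals * matrix(eps[w, ], spec$n_lat, spec$n_lon), spec, "ug/m3")
    }
  }
  list(annual = annual, weekly = weekly)
}

#' Generate sector-off concentration fields from the control
#'
#' Each sector-off field is `control * (1 - f_sector)`, with the cell-wise
#' fraction `f_sector` varying smoothly around the configured sector mean.
#' Cell-wise fractions are clipped to [0,1] and jointly rescaled where their
#' sum would exceed 1, so removing every sector never removes more than the
#' whole concentration.
#'
#' @param control Control [gridded_field()].
#' @param cfg A [synthetic_config()] with all seven `sector_fractions`.
#' @return A [scenario_set()].
#' @export
gen_sector_off_fields <- function(control, cfg) {
  stopifnot(inherits(control, "gridded_field"),
            inherits(cfg, "synthetic_config"))
  fr <- cfg$sector_fractions
  if (!setequal(names(fr), SECTOR_LABELS)) {
    stop("sector_fractions must name exactly: ",
         paste(SECTOR_LABELS, collapse = ", "))
  }
  spec <- control$spec
  set.seed(cfg$seed + 1L)
  fmat <- matrix(0, spec$n_lat * spec$n_lon, length(SECTOR_LABELS),
                 dimnames = list(NULL, SECTOR_LABELS))
  for (s in SECTOR_LABELS) {
    g <- correlated_noise(spec, cfg$spatial_correlation_length)
    f <- fr[[s]] * exp(0.1 * g - 0.005)    # mild spatial heterogeneity
    fmat[, s] <- pmin(pmax(as.vector(f), 0), 1)
  }
  tot <- rowSums(fmat)
  over <- tot > 1
  if (any(over)) fmat[over, ] <- fmat[over, ] / tot[over]
  off <- lapply(SECTOR_LABELS, function(s) {
    gridded_field(control$values * (1 - matrix(fmat[, s], spec$n_lat)),
                  spec, "ug/m3")
  })
  names(off) <- SECTOR_LABELS
  scenario_set(control, off)
}

# Largest-remainder (Hamilton) apportionment of `total` over weights w.
largest_remainder <- function(w, total) {
  stopifnot(total >= 0, all(w >= 0))
  if (sum(w) == 0) w <- rep(1, length(w))
  x <- total * w / sum(w)
  n <- floor(x)
  k <- round(total - sum(n))
  if (k > 0) {
    idx <- order(x - n, decreasing = TRUE)[seq_len(k)]
    n[idx] <- n[idx] + 1
  }
  n
}

#' Generate a gridded population field
#'
#' Smoothly varying rural density with a set of seeded dense urban cells
#' (above 400 persons/km^2), integer counts summing exactly to `total` by
#' largest-remainder allocation.
#'
#' @param spec A [grid_spec()].
#' @param total Total population (persons, >= 0). Default is 1.302e9.
#' @param cfg A [synthetic_config()]; `urban_fraction` controls the share of
#'   cells seeded as urban cores.
#' @return A [gridded_field()] of persons per cell.
#' @export
gen_population <- function(spec, total = 1.302e9, cfg = synthetic_config()) {
  stopifnot(inherits(spec, "grid_spec"))
  if (total < 0) stop("total population must be >= 0")
  set.seed(cfg$seed + 2L)
  ncell <- spec$n_lat * spec$n_lon
  g <- correlated_noise(spec, cfg$spatial_correlation_length)
  # settlement concentrates along the same plain that carries the pollution
  # band, so population-weighted exposure sits well above the area mean
  band <- matrix(rep(band_profile(spec), spec$n_lon), spec$n_lat, spec$n_lon)
  w <- exp(0.6 * g) * (1 + 0.25 * band)
  n_urban <- round(cfg$urban_fraction * ncell)
  if (n_urban > 0) {
    urban_idx <- sample.int(ncell, n_urban)
    w[urban_idx] <- w[urban_idx] * stats::runif(n_urban, 15, 60)
  }
  counts <- largest_remainder(as.vector(w), round(total))
  gridded_field(matrix(counts, spec$n_lat, spec$n_lon), spec, "persons")
}

# Per-disease log-normal medians for (alpha, beta, gamma). Right-skewed,
# strictly positive; purely synthetic stand-ins with IER-like saturation
# over the 10-300 ug/m3 ambient range.
ier_median_table <- function() {
  data.frame(
    disease = DISEASES,
    alpha = c(2.0, 0.9, 0.7, 0.45, 0.35),
    beta  = c(0.02, 0.018, 0.016, 0.010, 0.010),
    gamma = c(0.70, 0.85, 0.85, 1.00, 1.00)
  )
}

#' Generate a synthetic IER parameter ensemble
#'
#' Joint Monte-Carlo draws of the integrated exposure-response parameters
#' (alpha, beta, gamma) from right-skewed log-normal marginals, with the
#' counterfactual threshold TMREL drawn uniformly on [2.4, 5.9] ug/m3 per
#' draw. IHD and CEV receive age-specific parameter strata (excess risk
#' declining with age); ALRI, COPD and LC share one stratum across ages
#' (stored under age_group `"all"`). The marginals are synthetic stand-ins
#' with a realistic shape, not a reproduction of any published joint
#' parameter distribution.
#'
#' @param diseases Subset of [DISEASES].
#' @param age_groups Adult age groups used for the IHD/CEV strata.
#' @param n_draws Number of joint draws per stratum (>= 2). Default 1000.
#' @param seed Integer RNG seed.
#' @param sdlog Log-scale spread of the alpha/beta/gamma marginals.
#' @return An `ier_ensemble`: data frame of draws plus draw-count metadata.
#' @export
gen_ier_parameters <- function(diseases = DISEASES,
                               age_groups = ADULT_AGE_GROUPS,
                               n_draws = 1000L, seed = 1L, sdlog = 0.12) {
  if (n_draws < 2) stop("n_draws must be >= 2 (no uncertainty interval otherwise)")
  stopifnot(all(diseases %in% DISEASES))
  set.seed(seed)
  med <- ier_median_table()
  strata <- do.call(rbind, lapply(diseases, function(d) {
    if (d %in% c("IHD", "CEV")) {
      data.frame(disease = d, age_group = age_groups)
    } else {
      data.frame(disease = d, age_group = "all")
    }
  }))
  # age modifier: excess risk declines with age for the cardiovascular IERs
  age_mod <- function(d, a) {
    if (!d %in% c("IHD", "CEV") || a == "all") return(1)
    i <- match(a, ADULT_AGE_GROUPS)
    1.35 * 0.93^(i - 1)
  }
  rows <- vector("list", nrow(strata))
  for (r in seq_len(nrow(strata))) {
    d <- strata$disease[r]; a <- strata$age_group[r]
    m <- med[med$disease == d, ]
    rows[[r]] <- data.frame(
      disease = d, age_group = a, draw = seq_len(n_draws),
      alpha = stats::rlnorm(n_draws, log(m$alpha * age_mod(d, a)), sdlog),
      beta  = stats::rlnorm(n_draws, log(m$beta), sdlog),
      gamma = stats::rlnorm(n_draws, log(m$gamma), 0.6 * sdlog),
      tmrel = stats::runif(n_draws, 2.4, 5.9)
    )
  }
  as_ier_ensemble(do.call(rbind, rows))
}

#' Validate a draws table as an IER ensemble
#' @param df Data frame with columns disease, age_group, draw, alpha, beta,
#'   gamma, tmrel.
#' @return An `ier_ensemble`.
#' @export
as_ier_ensemble <- function(df) {
  need <- c("disease", "age_group", "draw", "alpha", "beta", "gamma", "tmrel")
  if (!all(need %in% names(df))) {
    stop("ensemble table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$alpha <= 0) || any(df$beta <= 0) || any(df$gamma <= 0)) {
    stop("alpha, beta and gamma must all be positive")
  }
  counts <- table(paste(df$disease, df$age_group))
  n <- unique(as.integer(counts))
  if (length(n) != 1) stop("all strata must hold the same number of draws")
  if (n < 2) stop("n_draws must be >= 2")
  rownames(df) <- NULL
  structure(list(draws = df, n_draws = n), class = "ier_ensemble")
}

# draws for a stratum, falling back to the shared "all" stratum
ensemble_draws <- function(ens, disease, age_group) {
  d <- ens$draws
  out <- d[d$disease == disease & d$age_group == age_group, ]
  if (nrow(out) == 0) out <- d[d$disease == disease & d$age_group == "all", ]
  if (nrow(out) == 0) stop("no draws for ", disease, "/", age_group)
  out
}

#' Generate a baseline mortality-rate table
#'
#' Cause- and age-specific baseline mortality rates (deaths per person-year)
#' with symmetric uncertainty bounds. ALRI is concentrated in the neonatal
#' and early-childhood groups; the adult causes rise steeply with age, with
#' magnitudes broadly typical of national all-cause composition.
#'
#' @param diseases Subset of [DISEASES].
#' @param age_groups Age-group labels.
#' @param rel_ui Half-width of the (lower, upper) bounds relative to the
#'   mean, e.g. 0.25 for mean +/- 25%.
#' @return Data frame (disease, age_group, mean, lower, upper), class
#'   `baseline_mortality`.
#' @export
gen_baseline_mortality <- function(diseases = DISEASES,
                                   age_groups = AGE_GROUPS,
                                   rel_ui = 0.25) {
  mid <- age_group_mid(age_groups)
  low <- age_group_lower(age_groups)
  rate_one <- function(d) {
    r <- switch(d,
      ALRI = ifelse(age_groups %in% c("EN", "LN", "PN"), 9e-3,
                    ifelse(age_groups == "1-4", 1.2e-3,
                           2e-5 + 4e-6 * pmax(mid - 50, 0))),
      IHD  = ifelse(low >= 25, 2.4e-4 * exp(0.072 * (mid - 25)), 0),
      CEV  = ifelse(low >= 25, 1.1e-4 * exp(0.080 * (mid - 25)), 0),
      COPD = ifelse(low >= 25, 1.5e-4 * exp(0.085 * (mid - 25)), 0),
      LC   = ifelse(low >= 25, 2.5e-5 * exp(0.070 * (mid - 25)), 0))
    r
  }
  out <- do.call(rbind, lapply(diseases, function(d) {
    m <- rate_one(d)
    data.frame(disease = d, age_group = age_groups, mean = m,
               lower = (1 - rel_ui) * m, upper = (1 + rel_ui) * m)
  }))
  rownames(out) <- NULL
  class(out) <- c("baseline_mortality", "data.frame")
  out
}

#' Generate a reference life table
#'
#' Remaining life expectancy (years) at the midpoint of each age group,
#' strictly decreasing with age, with ~86 years at birth as in aspirational
#' reference life tables.
#'
#' @param age_groups Age-group labels.
#' @param le_birth Life expectancy at birth (years).
#' @return Data frame (age_group, le), class `life_table`.
#' @export
gen_life_table <- function(age_groups = AGE_GROUPS, le_birth = 86.6) {
  mid <- age_group_mid(age_groups)
  # neonatal groups get distinct, slightly decreasing LE to keep the table
  # strictly monotone
  le <- pmax(le_birth - 0.92 * mid, 5) -
    0.01 * (match(age_groups, age_groups) - 1)
  out <- data.frame(age_group = age_groups, le = le)
  class(out) <- c("life_table", "data.frame")
  out
}

#' Generate a national age structure
#'
#' Population fraction per age group, normalised to sum to 1: a young,
#' broad-based pyramid with neonatal fractions tied to a ~1.9% annual birth
#' rate.
#'
#' @param age_groups Age-group labels.
#' @return Data frame (age_group, fraction), class `age_structure`.
#' @export
gen_age_structure <- function(age_groups = AGE_GROUPS) {
  birth_rate <- 0.019
  frac <- vapply(age_groups, function(g) {
    switch(g,
      "EN" = birth_rate * 7 / 365,
      "LN" = birth_rate * 21 / 365,
      "PN" = birth_rate * 337 / 365,
      "1-4" = 0.072,
      "80+" = 0.009,
      {
        low <- age_group_lower(g)
        0.095 * exp(-0.028 * low)   # smoothly thinning pyramid
      })
  }, 0, USE.NAMES = FALSE)
  out <- data.frame(age_group = age_groups, fraction = frac / sum(frac))
  class(out) <- c("age_structure", "data.frame")
  out
}

#' Generate synthetic observation sites from a field
#'
#' Samples the field bilinearly at random in-grid locations and adds
#' Gaussian noise, producing an annual value and four seasonal values per
#' site (seasonal values scatter around the annual one).
#'
#' @param field A [gridded_field()] to sample (the "truth").
#' @param n_sites Number of sites.
#' @param noise_sd Gaussian noise standard deviation (ug/m3).
#' @param seed Integer RNG seed.
#' @return Data frame (site_id, lat, lon, season, value) with seasons
#'   annual/DJF/MAM/JJA/SON.
#' @export
gen_observation_sites <- function(field, n_sites = 45L, noise_sd = 5,
                                  seed = 7L) {
  stopifnot(inherits(field, "gridded_field"), n_sites >= 1)
  set.seed(seed)
  spec <- field$spec
  lat <- stats::runif(n_sites, min(spec$lat), max(spec$lat))
  lon <- stats::runif(n_sites, min(spec$lon), max(spec$lon))
  base <- vapply(seq_len(n_sites), function(i) {
    sample_field(field, lat[i], lon[i], method = "bilinear")
  }, 0)
  seasons <- c("annual", "DJF", "MAM", "JJA", "SON")
  # seasonal amplitude: winter high, summer low, as in monsoon climates
  season_scale <- c(annual = 1, DJF = 1.4, MAM = 0.85, JJA = 0.6, SON = 1.15)
  out <- do.call(rbind, lapply(seasons, function(s) {
    v <- base * season_scale[[s]] + stats::rnorm(n_sites, 0, noise_sd)
    data.frame(site_id = seq_len(n_sites), lat = lat, lon = lon,
               season = s, value = pmax(v, 0))
  }))
  rownames(out) <- NULL
  out
}

#' Rectangular synthetic region boxes covering a grid
#'
#' Splits the domain into `n` vertical strips ("states") that exactly
#' partition the grid, returned as bounding boxes usable with
#' [write_region_geojson()] or [rasterise_boxes()].
#'
#' @param spec A [grid_spec()].
#' @param n Number of regions.
#' @return Named list of `c(lon_min, lat_min, lon_max, lat_max)` boxes.
#' @export
gen_region_boxes <- function(spec, n = 4L) {
  cuts <- seq(spec$lon_min, spec$lon_max, length.out = n + 1L)
  out <- lapply(seq_len(n), function(i) {
    c(cuts[i], spec$lat_min, cuts[i + 1L], spec$lat_max)
  })
  names(out) <- paste0("state_", seq_len(n))
  out
}

#' Rasterise rectangular region boxes to cell masks
#'
#' Cell-centre containment; a cell on a shared edge goes to the
#' first-listed region.
#'
#' @param boxes Named list of boxes as from [gen_region_boxes()].
#' @param spec A [grid_spec()].
#' @return Named list of logical masks.
#' @export
rasterise_boxes <- function(boxes, spec) {
  claimed <- matrix(FALSE, spec$n_lat, spec$n_lon)
  masks <- lapply(boxes, function(b) {
    inlon <- spec$lon >= b[1] & spec$lon <= b[3]
    inlat <- spec$lat >= b[2] & spec$lat <= b[4]
    m <- outer(inlat, inlon) & !claimed
    claimed <<- claimed | m
    m
  })
  names(masks) <- names(boxes)
  masks
}
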