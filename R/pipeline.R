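# End-to-end orchestration: generate synthetic inputs, compute exposure
# summaries, burden, sector apportionment, uncertainty-annotated totals and
# evaluation metrics, and write everything (plus a machine-readable
# manifest) to an output directory. Fully reproducible from the seed in
# the config.

#' Pipeline run configuration
#'
#' @param seed Master RNG seed; every stochastic stage derives its seed
#'   from it.
#' @param n_lat,n_lon Grid size.
#' @param total_population Total population allocated over the grid.
#' @param n_draws IER ensemble size.
#' @param n_regions Number of synthetic regions ("states").
#' @param n_sites Number of synthetic observation sites.
#' @param coarsen_factor Optional integer; if set, concentrations and
#'   population are block-coarsened by this factor before the burden step
#'   (resolution sensitivity).
#' @param cap Optional ceiling (ug/m3) applied to all concentration fields
#'   (concentration-capping sensitivity).
#' @param state_ratios Optional named region-to-nation baseline-rate ratios
#'   for COPD/IHD/CEV (regional-rates sensitivity).
#' @param cfg A [synthetic_config()]; its `seed` is overridden by `seed`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 42L, n_lat = 40L, n_lon = 40L,
                            total_population = 1.302e9, n_draws = 1000L,
                            n_regions = 4L, n_sites = 45L,
                            coarsen_factor = NULL, cap = NULL,
                            state_ratios = NULL,
                            cfg = synthetic_config()) {
  cfg$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), n_lat = as.integer(n_lat),
                 n_lon = as.integer(n_lon),
                 total_population = total_population,
                 n_draws = as.integer(n_draws),
                 n_regions = as.integer(n_regions),
                 n_sites = as.integer(n_sites),
                 coarsen_factor = coarsen_factor, cap = cap,
                 state_ratios = state_ratios, cfg = cfg),
            class = "pipeline_config")
}

write_csv_plain <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Run the full assessment pipeline
#'
#' generate -> exposure -> burden -> apportion -> uncertainty -> evaluate,
#' writing CSV artifacts and a JSON manifest under `out_dir`. Identical
#' configs (same seed) give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with the in-memory results (`exposure`,
#'   `burden`, `apportionment`, `totals`, `evaluation`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) if (!quiet) message("[pmburden] ", ...)

  # --- generate -----------------------------------------------------------
  log_stage("generate: grid ", config$n_lat, "x", config$n_lon,
            ", seed ", config$seed)
  spec <- grid_spec(config$n_lat, config$n_lon)
  ctrl <- gen_pm25_control(spec, config$cfg)
  scen <- gen_sector_off_fields(ctrl$annual, config$cfg)
  pop <- gen_population(spec, config$total_population, config$cfg)
  ens <- gen_ier_parameters(n_draws = config$n_draws,
                            seed = config$seed + 3L)
  bm <- gen_baseline_mortality()
  lt <- gen_life_table()
  ages <- gen_age_structure()
  boxes <- gen_region_boxes(spec, config$n_regions)
  masks <- rasterise_boxes(boxes, spec)
  sites <- gen_observation_sites(ctrl$annual, config$n_sites,
                                 seed = config$seed + 4L)
  weekly <- ctrl$weekly

  # --- sensitivity transforms --------------------------------------------
  if (!is.null(config$cap)) {
    log_stage("cap concentrations at ", config$cap, " ug/m3")
    capped <- lapply(scen$sector_off, cap_concentrations, cap = config$cap)
    scen <- scenario_set(cap_concentrations(scen$control, config$cap), capped)
    weekly <- lapply(weekly, cap_concentrations, cap = config$cap)
  }
  if (!is.null(config$coarsen_factor)) {
    f <- config$coarsen_factor
    log_stage("coarsen grid by factor ", f)
    off <- lapply(scen$sector_off, coarsen, factor = f,
                  mode = "concentration")
    scen <- scenario_set(coarsen(scen$control, f, "concentration"), off)
    pop <- coarsen(pop, f, "population")
    weekly <- lapply(weekly, coarsen, factor = f, mode = "concentration")
    masks <- rasterise_boxes(boxes, scen$control$spec)
  }

  # --- exposure -----------------------------------------------------------
  log_stage("exposure summary")
  expo <- exposure_summary(scen, pop)
  expo_extra <- data.frame(
    metric = c("pwm_control", "frac_pop_above_10", "frac_pop_above_35"),
    value = c(population_weighted_mean(scen$control, pop),
              exceedance_fraction(scen$control, pop, 10),
              exceedance_fraction(scen$control, pop, 35)))

  # --- burden -------------------------------------------------------------
  log_stage("burden (", config$n_draws, " draws)")
  bt <- compute_burden(scen$control, pop, ages, bm, ens, lt, masks,
                       state_ratios = config$state_ratios)

  # --- apportionment ------------------------------------------------------
  log_stage("sector apportionment (subtraction + attribution)")
  app <- apportion_all(scen, pop, ages, bm, ens, lt)

  # --- uncertainty --------------------------------------------------------
  log_stage("uncertainty (quadrature of fractional errors)")
  dshare <- burden_total(bt, "disease")
  wts <- stats::setNames(dshare$mortality, dshare$disease)
  pwm_ctrl <- expo_extra$value[1]
  conc_cells <- pm25_fractional_error(weekly, pop, per_cell = TRUE)
  comp <- list(
    population = 0.02,
    pm25 = propagate_conc_error(ens, conc_cells$mean, conc_cells$frac,
                                diseases = names(wts), weights = wts,
                                pop = conc_cells$pop),
    rr = rr_fractional_error(ens, pwm_ctrl,
                             diseases = names(wts), weights = wts),
    baseline = baseline_fractional_error(bm[bm$disease %in% names(wts), ],
                                         weights = wts))
  M_all <- sum(bt$mortality)
  yll_all <- sum(bt$yll)
  ui_m <- combine_burden_ui(M_all, comp)
  ui_y <- combine_burden_ui(yll_all, comp)
  totals <- data.frame(
    quantity = c("mortality", "yll"),
    mean = c(ui_m$mean, ui_y$mean),
    lower_95 = c(ui_m$lower_95, ui_y$lower_95),
    upper_95 = c(ui_m$upper_95, ui_y$upper_95))
  sect <- app$sectors
  for (col in c("m_subtraction", "m_attribution")) {
    sect[[paste0(col, "_lower")]] <- sect[[col]] * (1 - ui_m$fractional_error_low)
    sect[[paste0(col, "_upper")]] <- sect[[col]] * (1 + ui_m$fractional_error_high)
  }

  # --- evaluation ---------------------------------------------------------
  log_stage("evaluation vs synthetic sites")
  evalm <- evaluate_field(scen$control, sites)

  # --- write artifacts ----------------------------------------------------
  write_field(scen$control, file.path(out_dir, "pm25_control.grid"))
  write_field(pop, file.path(out_dir, "population.grid"))
  write_csv_plain(expo, file.path(out_dir, "exposure_summary.csv"))
  write_csv_plain(expo_extra, file.path(out_dir, "exposure_metrics.csv"))
  write_csv_plain(bt, file.path(out_dir, "burden_by_stratum.csv"))
  write_csv_plain(totals, file.path(out_dir, "burden_totals.csv"))
  write_csv_plain(sect, file.path(out_dir, "sector_apportionment.csv"))
  write_csv_plain(app$totals, file.path(out_dir, "method_totals.csv"))
  write_csv_plain(evalm, file.path(out_dir, "evaluation_metrics.csv"))
  write_ier_csv(ens, file.path(out_dir, "ier_ensemble.csv"))
  manifest <- list(
    package = "pmburden",
    version = as.character(utils::packageVersion("pmburden")),
    seed = config$seed,
    grid = c(config$n_lat, config$n_lon),
    total_population = config$total_population,
    n_draws = config$n_draws,
    coarsen_factor = config$coarsen_factor,
    cap = config$cap,
    sector_fractions = as.list(config$cfg$sector_fractions))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_stage("done: ", out_dir)
  invisible(list(exposure = expo, exposure_metrics = expo_extra,
                 burden = bt, apportionment = app, totals = totals,
                 sectors = sect, evaluation = evalm, manifest = manifest,
                 scenario = scen, population = pop, ensemble = ens))
}
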