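test_that("synthetic config rejects invalid parameters", {
  expect_error(synthetic_config(weekly_cv = -0.1), "weekly_cv")
  expect_error(synthetic_config(pollution_band_amplitude = -5), "amplitude")
  expect_error(synthetic_config(sector_fractions = c(TABLE1_FRACTIONS[-7],
                                                     TRA = 1.2)),
               "\\[0, 1\\]")
  expect_error(synthetic_config(sector_fractions = TABLE1_FRACTIONS * 2),
               "at most 1")
})

test_that("control field: weekly means close on the annual mean exactly", {
  spec <- grid_spec(12, 10)
  ctrl <- gen_pm25_control(spec, synthetic_config(seed = 5))
  expect_length(ctrl$weekly, 52)
  wk_mean <- Reduce(`+`, lapply(ctrl$weekly, function(f) f$values)) / 52
  expect_equal(wk_mean, ctrl$annual$values, tolerance = 1e-9)
  expect_true(all(ctrl$annual$values >= 0))
  expect_true(all(vapply(ctrl$weekly, function(f) min(f$values), 0) >= 0))
})

test_that("control field: zero weekly CV and zero amplitude degenerate cases", {
  spec <- grid_spec(6, 6)
  flat <- gen_pm25_control(spec, synthetic_config(weekly_cv = 0))
  for (w in c(1, 26, 52)) {
    expect_identical(flat$weekly[[w]]$values, flat$annual$values)
  }
  unif <- gen_pm25_control(spec, synthetic_config(
    background_level = 10, pollution_band_amplitude = 0))
  expect_true(all(unif$annual$values == 10))
})

test_that("control field: high-amplitude band exceeds 100 ug/m3 and is contiguous", {
  spec <- grid_spec(20, 20)
  ctrl <- gen_pm25_control(spec, synthetic_config(
    seed = 11, pollution_band_amplitude = 130, background_level = 15))
  over <- ctrl$annual$values > 100
  expect_true(any(over))
  # band rows: some latitude row entirely above 100
  expect_true(any(apply(over, 1, all)))
})

test_that("generation is deterministic under a fixed seed", {
  spec <- grid_spec(8, 8)
  cfg <- synthetic_config(seed = 99)
  a <- gen_pm25_control(spec, cfg)
  b <- gen_pm25_control(spec, cfg)
  expect_identical(a$annual$values, b$annual$values)
  expect_identical(a$weekly[[17]]$values, b$weekly[[17]]$values)
  expect_identical(gen_population(spec, 1e6, cfg)$values,
                   gen_population(spec, 1e6, cfg)$values)
  e1 <- gen_ier_parameters(n_draws = 10, seed = 3)
  e2 <- gen_ier_parameters(n_draws = 10, seed = 3)
  expect_identical(e1$draws, e2$draws)
})

test_that("sector-off fields are bounded by the control and recover the shares", {
  spec <- grid_spec(25, 25)
  cfg <- synthetic_config(seed = 21)
  ctrl <- gen_pm25_control(spec, cfg)
  scen <- gen_sector_off_fields(ctrl$annual, cfg)
  pop <- gen_population(spec, 1e9, cfg)
  total_removed <- 0
  for (s in SECTOR_LABELS) {
    off <- scen$sector_off[[s]]$values
    expect_true(all(off >= 0))
    expect_true(all(off <= ctrl$annual$values + 1e-12))
    total_removed <- total_removed + (ctrl$annual$values - off)
  }
  # removing every sector never removes more than the whole concentration
  expect_true(all(total_removed <= ctrl$annual$values + 1e-9))
  # population-weighted reductions recover the configured means
  for (s in c("BBU", "ENE", "IND", "RES", "TRA")) {
    r <- sector_reduction(scen, pop, s)
    expect_equal(r$fraction, unname(cfg$sector_fractions[s]),
                 tolerance = 0.05)
  }
})

test_that("uniform half fraction halves a uniform control; zero fractions are identity", {
  spec <- grid_spec(5, 5)
  ctrl <- gridded_field(100, spec)
  half <- uniform_scenario(ctrl, stats::setNames(rep(0.5, 7), SECTOR_LABELS))
  expect_true(all(half$sector_off$RES$values == 50))
  cfg0 <- synthetic_config(sector_fractions = stats::setNames(rep(0, 7),
                                                              SECTOR_LABELS))
  scen0 <- gen_sector_off_fields(ctrl, cfg0)
  for (s in SECTOR_LABELS) {
    expect_equal(scen0$sector_off[[s]]$values, ctrl$values)
  }
})

test_that("population conserves the requested total exactly and seeds urban cells", {
  spec <- grid_spec(10, 10)
  cfg <- synthetic_config(seed = 2, urban_fraction = 0.1)
  for (total in c(0, 1000, 1.302e9)) {
    pop <- gen_population(spec, total, cfg)
    expect_identical(sum(pop$values), as.numeric(round(total)))
    expect_true(all(pop$values >= 0))
  }
  pop <- gen_population(spec, 1.302e9, cfg)
  dens <- pop$values / cell_areas(spec)
  expect_true(sum(dens >= 400) >= 1)
  expect_error(gen_population(spec, -5, cfg), ">= 0")
  one <- gen_population(grid_spec(1, 1), 1000, cfg)
  expect_equal(one$values[1, 1], 1000)
})

test_that("IER ensemble: positivity, TMREL range, CSV round-trip, size errors", {
  ens <- gen_ier_parameters(n_draws = 50, seed = 8)
  d <- ens$draws
  expect_true(all(d$alpha > 0 & d$beta > 0 & d$gamma > 0))
  expect_true(all(d$tmrel >= 2.4 & d$tmrel <= 5.9))
  expect_identical(ens$n_draws, 50L)
  # every stratum has the same number of draws
  expect_true(all(table(paste(d$disease, d$age_group)) == 50))
  # IHD/CEV are age-resolved, the rest share one stratum
  expect_setequal(unique(d$age_group[d$disease == "IHD"]), ADULT_AGE_GROUPS)
  expect_identical(unique(d$age_group[d$disease == "COPD"]), "all")

  path <- withr::local_tempfile(fileext = ".csv")
  write_ier_csv(ens, path)
  back <- read_ier_csv(path)
  expect_equal(back$draws$alpha, d$alpha, tolerance = 1e-12)
  expect_identical(back$n_draws, 50L)

  expect_error(gen_ier_parameters(n_draws = 1), "n_draws")
  bad <- d
  bad$alpha[3] <- -1
  expect_error(as_ier_ensemble(bad), "positive")
})

test_that("baseline mortality, life table and age structure contracts hold", {
  bm <- gen_baseline_mortality()
  expect_true(all(bm$mean >= 0))
  expect_true(all(bm$lower <= bm$mean & bm$mean <= bm$upper))
  # adult-only causes carry zero rates below age 25
  young <- bm$age_group %in% c("EN", "LN", "PN", "1-4", "5-9")
  expect_true(all(bm$mean[bm$disease == "IHD" & young] == 0))
  expect_true(all(bm$mean[bm$disease == "ALRI"] > 0))

  lt <- gen_life_table()
  expect_true(all(lt$le > 0))
  expect_true(all(diff(lt$le) < 0))

  ages <- gen_age_structure()
  expect_equal(sum(ages$fraction), 1, tolerance = 1e-12)
  expect_true(all(ages$fraction >= 0))
})

test_that("observation sites reproduce the field exactly when noiseless", {
  spec <- grid_spec(10, 10)
  ctrl <- gen_pm25_control(spec, synthetic_config(seed = 3))
  sites <- gen_observation_sites(ctrl$annual, n_sites = 20, noise_sd = 0,
                                 seed = 9)
  ann <- sites[sites$season == "annual", ]
  sampled <- vapply(seq_len(nrow(ann)), function(i) {
    pmburden:::sample_field(ctrl$annual, ann$lat[i], ann$lon[i], "bilinear")
  }, 0)
  expect_equal(ann$value, sampled, tolerance = 1e-12)
  expect_setequal(unique(sites$season), c("annual", "DJF", "MAM", "JJA", "SON"))
})
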