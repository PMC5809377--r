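test_that("stratum mortality follows the attributable-fraction formula", {
  expect_equal(mortality_cell(1000, 0.01, 2), 5)
  expect_equal(mortality_cell(1000, 0.01, 1), 0)
  # RR -> Inf approaches the P*I ceiling from below
  expect_equal(mortality_cell(1000, 0.01, 1e9), 10, tolerance = 1e-6)
  expect_lt(mortality_cell(1000, 0.01, 50), 10)
  # monotone in RR
  rr <- seq(1, 5, by = 0.5)
  expect_true(all(diff(mortality_cell(100, 0.02, rr)) > 0))
  expect_error(mortality_cell(10, 0.01, 0.9), "RR")
  # the two algebraic forms of the attributable fraction agree
  rr <- runif(100, 1, 10)
  expect_equal((rr - 1) / rr, 1 - 1 / rr, tolerance = 1e-14)
})

test_that("urban classification applies the 400 persons/km2 threshold inclusively", {
  spec <- grid_spec(2, 2, lat_min = 0, lat_max = 2, lon_min = 0, lon_max = 2)
  area <- cell_areas(spec)
  vals <- matrix(c(399.9, 400.0, 0, 1000), 2, 2) * area
  pop <- gridded_field(vals, spec, "persons")
  urb <- classify_urban(pop)
  expect_identical(as.vector(urb), c(FALSE, TRUE, FALSE, TRUE))
  # halving densities (doubling area at fixed counts) can only lose cells
  half <- classify_urban(pop, threshold = 800)
  expect_true(all(half <= urb))
})

test_that("state scaling touches only the socioeconomically scaled causes", {
  bm <- gen_baseline_mortality()
  same <- apply_state_scaling(bm, c(A = 1), "A")
  expect_equal(same, bm)
  doubled <- apply_state_scaling(bm, c(A = 2, B = 1), "A")
  for (col in c("mean", "lower", "upper")) {
    sel <- bm$disease == "COPD"
    expect_equal(doubled[[col]][sel], 2 * bm[[col]][sel])
    keep <- bm$disease %in% c("LC", "ALRI")
    expect_equal(doubled[[col]][keep], bm[[col]][keep])
  }
})

test_that("total burden equals a brute-force loop over cells, diseases and ages", {
  spec <- grid_spec(20, 20)
  cfg <- synthetic_config(seed = 14)
  conc <- gen_pm25_control(spec, cfg)$annual
  pop <- gen_population(spec, 5e8, cfg)
  groups <- c("PN", "30-34", "60-64", "80+")
  ages <- tiny_ages(groups, c(0.05, 0.40, 0.35, 0.20))
  bm <- gen_baseline_mortality(age_groups = groups)
  lt <- gen_life_table(age_groups = groups)
  ens <- gen_ier_parameters(age_groups = intersect(groups, ADULT_AGE_GROUPS),
                            n_draws = 25, seed = 6)
  bt <- compute_burden(conc, pop, ages, bm, ens, lt)

  # independent oracle: nested loops, scalar IER evaluations per draw
  frac <- stats::setNames(ages$fraction, ages$age_group)
  le <- stats::setNames(lt$le, lt$age_group)
  M_oracle <- 0
  yll_oracle <- 0
  for (d in DISEASES) {
    age_ok <- if (d == "ALRI") groups else
      groups[age_group_lower(groups) >= 25]
    for (a in age_ok) {
      I <- bm$mean[bm$disease == d & bm$age_group == a]
      if (I == 0) next
      dr <- ens$draws[ens$draws$disease == d &
                        ens$draws$age_group %in%
                          (if (d %in% c("IHD", "CEV")) a else "all"), ]
      for (i in seq_len(spec$n_lat)) for (j in seq_len(spec$n_lon)) {
        c_ij <- conc$values[i, j]
        rr_mean <- mean(vapply(seq_len(nrow(dr)), function(k) {
          relative_risk(c_ij, dr$alpha[k], dr$beta[k], dr$gamma[k],
                        dr$tmrel[k])
        }, 0))
        M <- pop$values[i, j] * frac[[a]] * I * (rr_mean - 1) / rr_mean
        M_oracle <- M_oracle + M
        yll_oracle <- yll_oracle + M * le[[a]]
      }
    }
  }
  expect_equal(sum(bt$mortality), M_oracle, tolerance = 1e-9)
  expect_equal(sum(bt$yll), yll_oracle, tolerance = 1e-9)
})

test_that("burden respects cause-age applicability and the TMREL floor", {
  spec <- grid_spec(4, 4)
  groups <- c("PN", "30-34")
  ages <- tiny_ages(groups, c(0.3, 0.7))
  bm <- tiny_bm(c("ALRI", "IHD"), groups)
  lt <- tiny_lt(groups, c(80, 50))
  ens <- fixed_ens(0.5, 0.05, 1, 3, diseases = c("ALRI", "IHD"))
  pop <- gridded_field(1000, spec, "persons")

  # concentration at/below every TMREL draw: zero burden everywhere
  clean <- gridded_field(2, spec)
  bt0 <- compute_burden(clean, pop, ages, bm, ens, lt)
  expect_equal(sum(bt0$mortality), 0)

  # adult-only cause contributes nothing from the child age group
  conc <- gridded_field(50, spec)
  bt <- compute_burden(conc, pop, ages, bm, ens, lt)
  expect_true(all(bt$age_group[bt$disease == "IHD"] == "30-34"))
  expect_setequal(bt$age_group[bt$disease == "ALRI"], groups)

  # single-cell single-stratum reduction to mortality_cell
  spec1 <- grid_spec(1, 1)
  one <- compute_burden(gridded_field(50, spec1),
                        gridded_field(1000, spec1, "persons"),
                        tiny_ages("30-34", 1), tiny_bm("IHD", "30-34"),
                        fixed_ens(0.5, 0.05, 1, 3, diseases = "IHD"),
                        tiny_lt("30-34", 50))
  rr <- relative_risk(50, 0.5, 0.05, 1, 3)
  expect_equal(sum(one$mortality), mortality_cell(1000, 0.01, rr),
               tolerance = 1e-12)
  expect_equal(sum(one$yll), sum(one$mortality) * 50, tolerance = 1e-12)
})

test_that("burden is additive over a region partition and monotone in concentration", {
  spec <- grid_spec(12, 12)
  cfg <- synthetic_config(seed = 17)
  conc <- gen_pm25_control(spec, cfg)$annual
  pop <- gen_population(spec, 2e8, cfg)
  groups <- c("PN", "40-44")
  ages <- tiny_ages(groups)
  bm <- tiny_bm(c("ALRI", "COPD"), groups)
  lt <- tiny_lt(groups, c(80, 40))
  ens <- fixed_ens(0.8, 0.02, 1, c(3, 5), diseases = c("ALRI", "COPD"))
  masks <- rasterise_boxes(gen_region_boxes(spec, 3), spec)

  by_state <- compute_burden(conc, pop, ages, bm, ens, lt, masks)
  national <- compute_burden(conc, pop, ages, bm, ens, lt)
  expect_equal(sum(by_state$mortality), sum(national$mortality),
               tolerance = 1e-12)
  expect_setequal(unique(by_state$region), names(masks))

  # raising one cell's concentration never lowers the total
  bumped <- conc
  bumped$values[6, 6] <- bumped$values[6, 6] + 50
  bt2 <- compute_burden(bumped, pop, ages, bm, ens, lt)
  expect_gte(sum(bt2$mortality), sum(national$mortality))

  # state_ratios scale only the scaled causes within their region
  scaled <- compute_burden(conc, pop, ages, bm, ens, lt, masks,
                           state_ratios = c(state_1 = 2, state_2 = 1,
                                            state_3 = 1))
  sel <- function(bt, d, rg) sum(bt$mortality[bt$disease == d &
                                                bt$region == rg])
  expect_equal(sel(scaled, "COPD", "state_1"),
               2 * sel(by_state, "COPD", "state_1"), tolerance = 1e-12)
  expect_equal(sel(scaled, "ALRI", "state_1"), sel(by_state, "ALRI", "state_1"),
               tolerance = 1e-12)
})

test_that("YLL recomputation is linear in the life table", {
  groups <- c("PN", "40-44")
  bt <- data.frame(region = "all", class = "urban",
                   disease = c("ALRI", "COPD"), age_group = groups,
                   population = c(1e5, 2e5), mortality = c(10, 0),
                   yll = c(0, 0))
  class(bt) <- c("burden_table", "data.frame")
  lt <- tiny_lt(groups, c(80, 40))
  out <- yll_from_mortality(bt, lt)
  expect_equal(out$yll, c(10 * 80, 0))
  halved <- tiny_lt(groups, c(40, 20))
  expect_equal(yll_from_mortality(bt, halved)$yll, out$yll / 2)
  expect_error(yll_from_mortality(bt, tiny_lt("PN", 80)), "cover")
})
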