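# pmburden

Health-impact assessment of ambient fine particulate matter (PM2.5):
premature mortality and years of life lost (YLL) from gridded annual-mean
concentration fields, with the burden apportioned to emission sectors by
two contrasting methods.

The package is aimed at air-quality and environmental-epidemiology
researchers who have (or want to emulate) gridded PM2.5 fields from a
chemical-transport model — a control run plus per-sector "zero-out" runs —
together with gridded population, baseline mortality rates and an
exposure–response parameter ensemble.

## The model

Relative risk follows the saturating integrated exposure–response (IER)
form, per disease *j* and age group:

    RR(c) = 1                                   for c ≤ TMREL
    RR(c) = 1 + α·(1 − exp(−β·(c − TMREL)^γ))   for c > TMREL

evaluated over a Monte-Carlo ensemble of (α, β, γ, TMREL) draws (TMREL
uniform on 2.4–5.9 µg/m³). Attributable mortality in cell *i* is

    M_ij = P_i · I_j · (RR_jc − 1) / RR_jc ,     YLL_ij = M_ij · LE ,

summed over cells, diseases (ALRI all ages; IHD, CEV, COPD, LC for adults
≥ 25) and age groups. Sector burdens are computed both ways:

* **subtraction**: `M_SECTOR = M_ALL − M_SECTOR_OFF` (burden recomputed on
  the sector-off field);
* **attribution**: `M_SECTOR = M_ALL · (PM_ALL − PM_SECTOR_OFF) / PM_ALL`
  (total burden scaled by the sector's share of population-weighted
  exposure).

Because the IER saturates at high concentrations the two disagree —
attribution exceeds subtraction by a factor of roughly 2–2.5 where
population-weighted concentrations sit above ~50 µg/m³. 95% uncertainty
intervals combine fractional errors (population ±2%, weekly-concentration
spread pushed through the IER, exposure–response ensemble percentiles,
baseline-rate bounds) in quadrature, separately per side.

A synthetic-data module generates every input — correlated concentration
fields with a high-pollution band, weekly series, heterogeneous population
with dense urban cells, sector-off scenarios, parameter ensembles, rate
and life tables, observation sites — so the full pipeline runs offline and
deterministically from a seed. See `vignettes/pmburden-methods.Rmd` for
the full method description.

## Worked example

```r
library(pmburden)
res <- run_pipeline(pipeline_config(seed = 42), out_dir = "run")
res$exposure_metrics
#>              metric      value
#> 1       pwm_control 63.1381800
#> 2 frac_pop_above_10  1.0000000
#> 3 frac_pop_above_35  0.5690322
round(res$totals[, 2:4])
#>   quantity     mean lower_95 upper_95
#> 1 mortality   849061   275034  1280757
#> 2       yll 31604136 10237431 47672910
res$apportionment$totals
#>        method    total percent_of_control
#> 1 subtraction 516722.3                 61
#> 2 attribution 832231.3                 98
```

The synthetic population-weighted annual-mean exposure is 63.1 µg/m³; all
of the population is above the 10 µg/m³ air-quality guideline and 57%
above the 35 µg/m³ interim target. Attributable mortality is 849,061
deaths/yr (95UI 275,034–1,280,757) with 31.6 million YLL. Summed over the
seven sectors, the subtraction method recovers 61% of the control burden
while the attribution method reaches 98% — the saturation gap between the
two conventions. Per-sector results, stratum-level burden tables,
model-vs-observation statistics (NMB, Pearson *r*, best-fit slope) and a
JSON run manifest are written under `out_dir`.

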