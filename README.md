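# orchardgrowth

Thermal-time growth analysis of apple tree organs: when is growth
limited by resources, and what is each organ's maximum potential?

Orchard experiments answer this by removing competition — defruited
(DEF) and heavily thinned (THI) trees against fruited controls (FRU) —
and comparing organ growth rates on a physiological clock. This package
implements the full analysis chain for such an experiment, together
with a synthetic-orchard generator with known ground truth so every
stage can be validated by recovery tests.

## What it computes

* **Thermal time**: daily growing degree days from hourly air
  temperature, each hourly value clamped into [4.5, 35] °C before
  averaging and subtracting the 4.5 °C base, accumulated from full
  bloom (`accumulate_gdd()`).
* **Allometric dry mass**: spheroid fruit volume
  (V = 4/3 π r₁r₂r₃), the trunk power law
  AGB = 202.9379 · (c/π)^1.6115 (c in cm, AGB in g), and AIC-selected
  calibration models — shoots on length, log(length), GDD and their
  interaction; fruits on log(volume), GDD and treatment
  (`fit_dry_weight_model()`).
* **Relative rates**: interval RER/RGR,
  (ln x₂ − ln x₁)/(g₂ − g₁), assigned to interval midpoints; log-linear
  trunk RGR fits; normalized trunk circumference; sustained
  elongation-cessation detection at RER < 10⁻² °C·day⁻¹
  (`trajectory_rates()`, `fit_log_linear_rgr()`).
* **Maximum potential**: spur filtering (> 4 cm, strict),
  proleptic/epicormic classification from pruning traces, top-5 shoots
  per class by final dry mass, the Max trunk tree by normalized
  circumference increment, the mean THI fruit curve, and the
  fruit-variability regressions (`select_max_shoots()`,
  `select_max_trunk()`, `fruit_variability_analysis()`).
* **Treatment statistics**: per-date one-sided Mann–Whitney (shoot RER)
  and Welch t-tests (fruit RGR), Bonferroni-adjusted within each
  comparison series, with significance stars (`compare_series()`).
* **Synthetic orchard**: seeded generator of weather, shoot (Gompertz),
  fruit (expolinear with fruit-set jitter) and trunk (exponential)
  trajectories plus measurement noise, with a complete ground-truth
  record (`simulate_orchard()`, `ground_truth()`).

## Worked example

The numbered scripts under `analysis/` run the whole study on a
simulated orchard and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_orchard.R
Rscript analysis/02_thermal_time.R
Rscript analysis/03_calibration_models.R
Rscript analysis/04_growth_report.R
```

Stage 4 prints (seed 20141):

```
== shoot elongation ==
  mean RER fell below 1e-2 per GDD at: FRU 299, DEF 299 GDD
  DEF > FRU shoot RER significant at 10 of 10 dates (from 166 GDD)

== maximum potential shoots (defruited population) ==
  Max proleptic  final masses 9.2, 7.9, 7.7, 7.6, 7.6 g; late-season mean RGR 3.47e-04
  Max epicormic  final masses 17.0, 17.0, 16.8, 16.7, 14.5 g; late-season mean RGR 1.12e-03

== fruit growth ==
  THI > FRU fruit RGR significant at 1 of 9 dates
  harvest ~ initial mass slope +4.71 (p = 3.5e-05)
  initial ~ early RGR slope -180.0 (p = 6.1e-22)

== trunk growth ==
  treatment effect on relative increment: p = 1.6e-06; GDD: p = 7.3e-20
  woody-biomass RGR: FRU 2.70e-05, DEF 4.92e-05 (DEF/FRU = 1.8)
  Max tree DEF_T002: RGR 7.08e-05 (44% above DEF mean)

  recovery check: selected Max trunk DEF_T002 vs generating max DEF_T002
```

Reading this: defruited shoots keep a significantly higher relative
elongation rate than fruited ones across the season; epicormic Max
shoots sustain a late-season RGR about three times the proleptic Max
(they are still elongating when proleptics have stopped); the spread in
thinned-fruit harvest mass traces back to first-date mass, which in
turn is *negatively* related to early RGR — the signature of staggered
fruit set rather than resource limitation; and the defruited trunks
outgrow fruited ones, with the fastest tree correctly recovered from
the measurements.

A programmatic equivalent:

```r
library(orchardgrowth)
sim <- simulate_orchard(orchard_config(), seed = 1)
rep <- run_report(sim$measurements, sim$orchard$weather,
                  sim$orchard$config$bloom_date, sim$calibration)
rep$shoots$comparison     # per-date Mann-Whitney table with stars
rep$trunk$max             # the Max tree and its log-linear RGR fit
```

## Package layout

`R/` implementation; `tests/testthat/` unit, property and acceptance
suites (all fixtures generated in code); `analysis/` numbered workflow
drivers; `vignettes/growth-analysis-methods.Rmd` the methods notes —
model assumptions, parameter choices, and what the synthetic-data
recovery tests do and do not demonstrate.
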