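---
title: "Methods: thermal-time growth analysis of apple tree organs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal-time growth analysis of apple tree organs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Fruit-tree organs (current-year shoots, fruits, the woody trunk) compete
for carbohydrates. Whether an organ grows at the pace set by its own
sink capacity ("sink-limited", the maximum potential) or at a pace
restricted by assimilate supply ("source-limited") can be diagnosed by
comparing relative growth rates (RGR) between trees with reduced
competition (defruited, DEF; heavily thinned, THI) and untouched
controls (FRU). This package implements that comparison pipeline for an
apple orchard: a thermal-time axis, allometric dry-mass estimation from
non-destructive size measurements, interval relative rates, per-date
treatment tests, and the extraction of maximum-potential growth curves —
plus a synthetic orchard generator with known ground truth so the whole
chain can be validated by recovery tests.

## Thermal time

All analyses run on accumulated growing degree days (GDD) after full
bloom. Daily GDD is the mean of the hourly mean temperatures, each
clamped into [`base_temp`, `upper_cutoff`] = [4.5, 35] °C, minus the
base; it is therefore bounded in [0, 30.5] °C·day. Sub-hourly records
are averaged to hourly means *before* clamping.

Numerical and policy choices:

* "Cutoff of values outside the range" is implemented as **clamping**
  (saturation). Discarding out-of-range hours would bias cold days
  upward (a night at 2 °C would simply vanish from the average) and is
  not standard degree-day practice; a `cutoff_mode = "discard"` option
  exists for sensitivity analysis.
* Daily GDD is credited at the **end of its day**, and measurement
  dates map to end-of-day cumulative GDD; measurements are
  daily-resolution, so any finer attribution would be spurious.
* A day is usable when at least 18 of 24 hours are present; fewer is an
  error rather than a silently biased mean.

## Allometric dry-mass estimation

Fruit volume is the rotational-spheroid formula
\(V = \tfrac{4}{3}\pi r_1 r_2 r_3\) on three orthogonal caliper
diameters (mm). Woody above-ground biomass uses the fixed power law
\(\mathrm{AGB} = a\,(c/\pi)^b\) with \(a = 202.9379\) g and
\(b = 1.6115\), circumference \(c\) in cm; these coefficients are taken
as given (established for the same orchard) and are *not* refitted in
the core path. With \(c\) in cm and mass in g a 25 cm-girth trunk comes
out near 5.7 kg, which is the realistic scale for a mature tree on a
dwarfing rootstock.

Shoot and fruit dry-weight models are fitted to destructive calibration
samples by maximum likelihood with AIC selection over nested candidate
term sets:

* shoots: length, log(length), GDD and the log(length) × GDD
  interaction (the `*` shorthand is expanded to main effects plus
  interaction, the standard model-formula convention; an
  interaction-only variant is available);
* fruits: log(volume), GDD, treatment and treatment × GDD.

The shoot default family is gaussian-identity; the fruit default is
**Gamma with log link**. Fruit dry mass spans three orders of magnitude
over the season, and an identity-link fit on log-volume terms produces
negative predicted masses for early fruitlets, which the downstream
log-based rates cannot accept; the log link keeps predictions strictly
positive and matches the multiplicative error structure of oven-dry
masses. Natural logarithms are used throughout. The shoot model is
fitted on FRU calibration samples only and applied to DEF shoots as a
deliberate lower bound (DEF shoots are slightly thicker at equal
length; the one-sided density comparison in `density_comparison()`
checks they are not denser).

## Relative rates

For sizes \(x_1, x_2\) at thermal times \(g_1 < g_2\), the interval
rate is \((\ln x_2 - \ln x_1)/(g_2 - g_1)\): RER for lengths, RGR for
dry masses, in units of °C·day\(^{-1}\). Rates are assigned to the
**interval midpoint** (symmetric, standard in classical growth
analysis; the sources do not specify an assignment). Negative rates are
retained — fruit dry weight can genuinely decline near harvest.
Rescaling all sizes by a positive constant leaves every rate unchanged,
and summing rate × interval width reconstructs \(\ln(x_n/x_1)\)
exactly; both properties are tested.

Trunk RGR is the OLS slope of mean ln(AGB) against GDD (per treatment
through per-date means across trees, per tree for the Max path).
Elongation cessation is declared at the first interval from which RER
stays below \(10^{-2}\) °C·day\(^{-1}\) for *all* remaining intervals —
a single noisy dip does not count. The mixed per-mille unit string
sometimes attached to RER thresholds is treated as the plain
length-relative rate per degree-day, since any common length unit
cancels in the ratio.

## Maximum-potential extraction

* **Spur filter**: shoots are retained only if their final length is
  *strictly* greater than 4 cm ("longer than" is read strictly;
  configurable).
* **Classification**: shoots on branches with pruning traces are
  potentially epicormic, all others proleptic; a missing flag yields
  "unknown" and exclusion from selection.
* **Max shoots**: per class, the five shoots with the highest final dry
  mass, pooled across all DEF trees (a per-tree split is not supported;
  pooling matches the small per-class populations). Ties break by final
  length, then organ id, making the selection deterministic and
  idempotent.
* **Max trunk**: the tree with the highest final increment in
  normalized circumference (\(c_t/c_0 - 1\)); its fitted log-linear RGR
  is reported alongside but is not the selection metric.
* **Fruit**: the simple mean RGR curve over all non-pest-damaged THI
  fruits. A top-k subset is wrong here because much of the THI spread
  reflects fruit-set timing: the variability diagnostics regress
  harvest mass on first-date mass (expected positive) and first-date
  mass on the first-interval RGR (expected negative). "Early-season
  RGR" is defined as the first measured interval's RGR.

## Treatment comparisons

Per shared measurement interval: one-sided unpaired Mann–Whitney tests
for shoot RER (DEF > FRU) and one-sided Welch t-tests for fruit RGR
(THI > FRU), with Bonferroni correction whose family is the number of
intervals *within that comparison series* (not all tests in the study —
each organ/figure is its own family). The Mann–Whitney contract is
explicit: exact distribution when \(n_a + n_b \le 16\) with no ties
(equal to full permutation enumeration, which the tests verify
exhaustively up to \(n = 8\)), tie-corrected normal approximation
otherwise. Welch rather than pooled variance because equal spread
across treatments is exactly what the design perturbs. Stars are
\(\le 0.001\) ***, \(\le 0.01\) **, and \(\le 0.05\) * — the single-star
cut is the conventional completion of the two documented thresholds.
Intervals are aligned by index with a GDD tolerance; drifting schedules
beyond tolerance are an error, not a silent merge.

## The synthetic orchard

The generator reproduces the *statistical structure* the analysis
assumes, with every latent parameter recorded for recovery testing. Its
defaults are the study conditions: 5 trees per treatment, 20 tagged
shoots per FRU/DEF tree (about 15% of tags turn out to be spurs),
9 tagged fruits per FRU/THI tree, trunk collars on FRU/DEF, biweekly
measurements from two weeks after bloom relaxing to monthly in late
summer, and an early-April bloom in a climate with ~12 °C annual mean
(sinusoidal seasonal trend, mid-afternoon diurnal peak, seeded noise).
Under the default weather the season accumulates ≈ 2400 GDD and the
defruiting date (three weeks after bloom) sits near 160 GDD.

Latent shapes:

* **Shoot length** is Gompertz in GDD, so RER \(= A k e^{-kg}\)
  declines smoothly from bloom. Fruited proleptics cease elongation
  first, defruited proleptics later and 28% longer, epicormics (30% of
  DEF shoots, on pruned branches) elongate into late summer — which is
  what makes their late-season RGR exceed the proleptic Max selection,
  the qualitative contrast the recovery test checks.
* **Shoot mass** follows the fixed rule
  \(W = c_1 L + c_2 \log(1+L)\,g\) — strictly positive, close to but
  deliberately not identical to the calibration model's log-length term
  set, so model fitting faces realistic mild misspecification.
* **Fruit mass** is expolinear in fruit age \(u = g - g_{set}\):
  \(W = (s/r_m)\ln(1 + e^{r_m(u - t_b)})\), maximum RGR \(r_m\)
  (THI 0.021, FRU 0.015 °C·day\(^{-1}\)), linear slope \(s\) (0.035 /
  0.022 g per °C·day) reaching ≈ 60 g (THI) and ≈ 40 g dry at harvest,
  about 55% apart, with transition age \(t_b = 150\) °C·day. Fruit set
  jitters uniformly over 40–180 GDD; because expolinear RGR declines
  monotonically with age, later-set fruits are lighter at first
  measurement *and* faster-growing — generating the negative
  initial-mass ~ early-RGR relation the diagnostics look for. A
  late-season mass decline is available as an option but off by
  default: it contradicts the pure expolinear form and is kept as a
  sensitivity switch.
* **Trunk biomass** is exponential in GDD with treatment RGR
  \(7.4\times10^{-5}\) (DEF) vs \(2\times10^{-5}\) (FRU) °C·day
  \(^{-1}\) (a ~270% contrast) and a lognormal tree effect of CV 0.4,
  chosen so the expected maximum of five trees sits ~55–60% above the
  treatment mean — the contrast reported for the field Max tree.
  Circumference is obtained by inverting the wood power law, so trunk
  ground truth is exact.

Measurement noise is multiplicative lognormal (length CV 3%, diameters
2%, trunk circumference 0.2% — collars are read at sub-millimetre
precision on a ~25 cm girth — calibration dry mass 5%), fruit diameters
are emitted as three volume-preserving jittered orthogonal diameters,
and 8% of fruits carry pest-damage flags. All randomness flows from one
root seed through named substreams (weather, organs, measurement
noise), so a dataset is a pure function of (config, seed).

What the generator does **not** emulate: weather gaps and sensor
failure, within-canopy light gradients (canopy level is a label, not a
driver), correlated measurement errors by observer or date, true
biological shapes beyond the Gompertz/expolinear/exponential families,
and any carbon-allocation feedback between organs. Passing recovery
tests therefore shows the *pipeline* is correct and well-calibrated,
not that these families describe real orchards.

## Problem sizes and numerical choices

The test suite validates each operation against independent oracles
(explicit-loop daily GDD, full permutation enumeration for
Mann–Whitney, closed-form normal equations for every OLS slope) and
runs the full pipeline recovery on 100 seeded replicates of the default
orchard (≈ 300 organs each); family-wise error control is estimated on
500 replicates of a null 5-vs-5, 8-date comparison. These sizes give
Monte-Carlo standard errors comfortably below the tested margins.
Degenerate inputs have defined behaviour: zero-variance t-tests return
p = 0.5 with a warning, empty rate series propagate as empty results
with warnings, rank-deficient calibration designs and constant
regression predictors are errors, and shoot-mass predictions at or
below zero (possible under the identity link for the smallest early
shoots) are floored at 1 mg with a message rather than silently
dropped.

## Known limitations

* The wood allometry's printed coefficients are dimensionally
  convention-bound; this package fixes circumference in cm and mass in
  g and exposes overrides, but cannot verify the original units.
* Independent per-date tests ignore the repeated-measures correlation
  within organs; with Bonferroni correction this is conservative for
  the family-wise error but not efficient. A mixed-model alternative is
  deliberately out of scope.
* The DEF shoot masses are lower-bound estimates by construction; DEF
  vs FRU RGR contrasts are therefore conservative too.
* AIC-based selection retains a superfluous nested parameter with its
  nominal ≈ 16% probability; the candidate sets are small and
  hand-chosen, not an exhaustive search.
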