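---
title: "A bioenergetic model of hypoxia effects on Acartia tonsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bioenergetic model of hypoxia effects on Acartia tonsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acartia)
```

## The model

Coastal hypoxia — dissolved oxygen low enough to impair aquatic life — is
usually flagged by a concentration standard (< 2 mg L⁻¹), but what an
ectotherm actually experiences is limitation of diffusive oxygen supply,
which is governed by oxygen *partial pressure* and modulated by temperature.
This package implements a bioenergetic model for the coastal copepod
*Acartia tonsa* that turns temperature, salinity, and oxygen partial
pressure into predicted vital rates.

The core idea: below some ambient PO₂, the maximum rate at which an animal
can take up oxygen is set by diffusion and is therefore *linear* in PO₂.
For *A. tonsa* at the 18 °C reference this maximum respiration line is

$$ARR = a \cdot PO_2 + b, \qquad a = 34.9,\; b = -20.5$$

in µg O₂ mg dw⁻¹ d⁻¹ (`arr_at()`, floored at zero below the line's root at
~0.59 kPa). *ARR* stands for **analogous respiration rate**: any vital rate
(egg production, somatic growth, ingestion) re-expressed in the oxygen
units it implies through fixed bioenergetic conversion factors. Expressing
heterogeneous literature measurements in a common currency is what lets a
single line be estimated from egg-production, growth, and feeding
experiments at once.

Two reference respiration rates anchor the thresholds, both at 18 °C:

* **TRR** (target respiration rate, 261.5 µg O₂ mg dw⁻¹ d⁻¹): average
  respiration of healthy, fed animals. The PO₂ where the line crosses TRR
  is the **critical partial pressure** $P_{crit}$ — below it, respiration
  (and hence egg production and growth) is oxygen-limited.
* **MRR** (minimum survivable respiration rate, 91.0): average respiration
  of persistently starved animals. The crossing with MRR is the **lethal
  partial pressure** $P_{leth}$ — below it, mortality rises.

Temperature moves metabolic demand with a salinity-dependent Q10
(1.5 at salinity 15, 2.03 at 25, 2.22 at 35; linearly interpolated in
between, clamped outside), so the thresholds are

$$P_{crit}(T,S) = \frac{TRR \cdot Q_{10}(S)^{(T-18)/10} - b}{a}, \qquad
  P_{leth}(T,S) = \frac{MRR \cdot Q_{10}(S)^{(T-18)/10} - b}{a}.$$

At 18 °C these are 8.1 and 3.2 kPa. Below $P_{leth}$ the 24-h probability of
copepodite mortality interpolates linearly *in respiration space* from 0 at
$P_{leth}$ to 1 at $P_{leth}/2$ (`mortality_24h()`); because the line itself
is linear, this is also linear in PO₂. Below $P_{crit}$, oxygen-limited egg
production and somatic growth are back-converted from the line:

$$EPR = ARR / 264 \;(= 0.00379\,ARR), \qquad
  G = ARR \cdot \tfrac{NGE}{1-NGE} \cdot RQ_m \;(= 1.014\,ARR).$$

```{r}
hypoxia_thresholds(c(5, 18, 25), S = 25)
predict_hypoxia_effects(
  data.frame(temperature = 18, salinity = 10, po2 = c(15, 5, 2)))
```

## Parameters and their provenance

All constants live in one overridable record, `model_constants()`, also
loadable from YAML (`load_constants()`); the packaged
`extdata/default_constants.yml` is the published *A. tonsa*
parameterization. The ones a user is most likely to touch:

| field | default | units | meaning |
|---|---|---|---|
| `slope_a`, `intercept_b` | 34.9, −20.5 | µg O₂ mg dw⁻¹ d⁻¹ (per kPa) | maximum-respiration line at 18 °C |
| `TRR`, `MRR` | 261.5, 91.0 | µg O₂ mg dw⁻¹ d⁻¹ | threshold-defining rates at 18 °C |
| `q10_table` | (15, 1.5), (25, 2.03), (35, 2.22) | — | salinity-dependent Q10 |
| `regression_cutoff` | 8 | kPa | strict upper PO₂ bound of the oxygen-limited region |
| `egg_resp_cost` | 264 | µg O₂ mg egg dw⁻¹ | respiratory cost of egg production |
| `NGE`, `RQ_mass` | 0.75, 0.338 | —, µg C µg O₂⁻¹ | growth back-conversion factors |
| `p_o2_sat` | 20.95 | kPa | air-saturation O₂ partial pressure |
| `pcrit_se`, `pleth_se` | 1.7 | kPa | quoted threshold standard errors (carried, not recomputed) |

The Discussion-style use case — substituting a locally measured line — is
supported by `fit_max_resp()` + `fit_to_constants()`; the packaged
coefficients are never replaced implicitly.

## Converting measurements to ARR

`observations_to_arr()` applies, per row of an observation table:

* egg production (eggs f⁻¹ d⁻¹) × egg dry weight (0.104 µg) × cost
  (264 µg O₂ mg egg dw⁻¹) ÷ female dry weight at the experiment
  temperature (dw = 8.67 − 0.25 T µg). The division uses the
  *experiment-temperature* dry weight, since the weight relation is itself
  temperature-dependent.
* somatic growth (mm³ cop⁻¹ d⁻¹) × 167.6 µg dw mm⁻³ × 0.4 µg C µg dw⁻¹ ÷
  mean animal dry weight, then ÷ 1.014. Mean dry weight is an explicit
  per-observation column: the published stage-averaged weights
  (0.283–0.416 µg) are not unambiguously paired with treatments, so the
  package never guesses one.
* ingestion (µg C mg dw⁻¹ d⁻¹) through the affine respiration relation
  R = 0.07 I + 33.39, ÷ 0.338 µg C µg O₂⁻¹. Note zero ingestion maps to the
  basal term 98.8, not zero.

Each ARR is then Q10-standardized to 18 °C with the salinity-matched Q10
(`standardize_to_ref()`), and `arr_group_means()` averages by study ×
PO₂ (PO₂ matched after rounding to 2 decimals, the reporting precision of
experimental target pressures). Group means are n-weighted, which makes the
operation idempotent and lets literature values reported only as means
coexist with raw measurements. The same factors back-convert predictions
(`egg_production()`, `somatic_growth()`), so conversion and prediction are
exact inverses by construction.

## Oxygen units

`o2_convert()` moves among kPa, % air saturation, mg L⁻¹, and mL L⁻¹.
kPa ↔ %sat is linear through `p_o2_sat` and needs no hydrography.
Concentration conversions go through the Benson–Krause solubility equation
(the formulation behind the USGS DOTABLES tables), implemented in
`o2_saturation_concentration()`, and *require* temperature and salinity —
the functions refuse to assume them. mL L⁻¹ ↔ mg L⁻¹ uses the fixed O₂
density 1.42905 mg mL⁻¹. All conversions assume 1 atm total pressure
(surface incubations); no depth correction is attempted.

## Grazing experiments

`grazing_rates()` implements the classical bottle-incubation closed form:
apparent algal growth k from controls, grazing coefficient
g = k − ln(c_t/c₀)/t per copepod bottle, time-averaged concentration
$\bar{C} = c_0\,(e^{(k-g)t}-1)/((k-g)t)$ (continuously c₀ at the removable
singularity k = g, evaluated with a series below |x| < 10⁻⁸), clearance
F = V g/N and ingestion I = F·C̄, converted to dry-weight-specific carbon
units with 55 pg C cell⁻¹ and the temperature-dependent female dry weight.
The control rate per experiment pools *all* control bottles (both oxygen
levels), following the observation that control growth does not differ
between them. Negative grazing (a treatment bottle outgrowing controls) is
reported with a `negative_grazing` flag rather than clipped — a
transparency choice for quality control. `compare_treatments()` offers
pooled, Welch, and paired-by-experiment t-tests; the paired mode is the one
consistent with a small-df design of a few experiments each contributing
one treatment mean.

## What the synthetic generators emulate

The package ships seeded generators for every input it consumes, so all
pipelines are exercised without any external data.

`gen_vital_rates()` mirrors the *structure* of the compiled literature
dataset behind the line fit: 17 (study × PO₂) groups from 153 individual
measurements, spread over two egg-production studies, one growth study
(with stage-averaged dry weight), and one ingestion study, at PO₂ between
2.2 and 7.8 kPa. ARR values are drawn at 18 °C around the true line and
back-converted through the exact inverse chains into native units, so the
forward pipeline recovers them bit-for-bit and, with `noise_sd = 0`, the
whole observation → ARR → fit → threshold chain is an exact round trip.

Noise is hierarchical: one group-level deviation ~N(0, σ) shared by a
(study × PO₂) group plus independent per-measurement noise of the same σ
(default 25 µg O₂ mg dw⁻¹ d⁻¹). The group-level term represents
between-study methodological differences, which is what keeps group *means*
realistically scattered about the line (R² typically 0.7–0.9, comparable to
the published fit) even when groups are large; purely per-measurement noise
would average away and give R² near 1, which real compilations do not show.
Ingestion groups are placed at PO₂ ≥ 5.2 kPa so that back-conversion
through the affine ingestion relation stays in its valid (non-negative)
range. Optional above-cutoff groups draw uniformly between 0.8·TRR and the
line value, emulating the high, variable rates seen under ample oxygen.

`gen_bottles()` mirrors the feeding-experiment design — three experiments
of 12 bottles (3 grazing + 3 controls per oxygen treatment), 610 mL, 12
females per bottle, 1921 cells mL⁻¹ initial algae at 55 pg C cell⁻¹,
18.5 °C — with true treatment ingestion rates (defaults 511 and 146 µg C
mg dw⁻¹ d⁻¹) inverted through the closed form to exact exponential count
trajectories. Counting error is multiplicative lognormal (mean-preserving)
on final counts, reflecting that electronic particle counts at ~2000
cells mL⁻¹ have relative rather than Poisson-dominated error. Incubations
default to 2 d, the longer of the reported 1–2 d designs, which integrates
the grazing signal over more e-foldings relative to counting noise.

`gen_env_samples()` draws (T, S, PO₂) per stratum from truncated Gaussians;
degenerate (sd = 0) strata pin classifier ground truth exactly.

What the generators do **not** emulate: real monitoring-station
climatology, covariance between temperature and oxygen in stratified
estuaries, within-study autocorrelation, or non-Gaussian rate
distributions. Passing recovery tests therefore demonstrates correctness of
the estimation pipeline under the stated error model, not robustness to
every feature of field data.

## Numerical and design choices

* The regression cutoff is *strict* (`po2 < 8`), and the fit is unweighted
  across group means irrespective of group size, matching how the packaged
  line was estimated.
* Thresholds are computed at full precision and rounded only for display:
  the chained published values (e.g. 3.6 kPa at 5 °C) only reproduce from
  unrounded intermediates. Consequently mortality at the *rounded* 1.6 kPa
  endpoint is 0.998, displayed as 100 %.
* Q10 outside salinity 15–35 clamps to the nearest endpoint; no
  extrapolation, following how the source table is described.
* Classification boundaries: `po2 == pcrit` → none; `po2 == pleth` →
  sublethal (mortality is exactly 0 there). Rate predictions are `NA` above
  `pcrit`, where the oxygen-limited line does not apply.
* The mortality interpolant is clamped to [0, 1]; the raw value is
  available via `mortality_24h(..., raw = TRUE)` since values ≥ 1 simply
  mean certain death within 24 h. Mortality estimates apply to copepodites;
  nauplii tolerate lower oxygen and are outside the model.
* Generators save and restore the caller's RNG state, so they are pure
  functions of their seed.

Test problem sizes: recovery checks use 200 seeded replicates of the
17-group fixture (regression) and 200 seeded bottle sets at cv = 0.1
(grazing); both run in seconds and give Monte-Carlo error well below the
asserted tolerances (2 % and 5 %).

## Limitations

* Parameterized for *A. tonsa* only; the only allometry is the female
  dry-weight–temperature line. Applying the framework to another species
  requires a new constants file and, ideally, a locally fitted line.
* The quoted ±1.7 kPa threshold SEs are carried as constants; no error
  propagation through the Q10 scaling is attempted.
* The mortality model is a 24-h exposure dose–response; it says nothing
  about avoidance behaviour, vertical migration, or chronic exposure.
* Egg hatching success, which also declines under hypoxia, is not
  modelled.
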