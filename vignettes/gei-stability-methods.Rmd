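---
title: "Methods: GEI, stability statistics and the savanna maize simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GEI, stability statistics and the savanna maize simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxemaize)
```

This vignette documents the models behind `gxemaize`, the assumptions they
make, the parameters a user may want to turn, and the design decisions that
were genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The statistical layer

### Variance partitioning

A balanced trial of `p` genotypes x `q` environments x `r` replicates is
partitioned by `two_way_anova()` into Genotype, Environment, GEI, Rep and
Error sums of squares, fitted via `stats::aov()` (with balance, sequential
SS are the orthogonal decomposition). Two conventions deserve a note:

* **Replicate is a crossed block** (df `r − 1`, error df `(pq − 1)(r − 1)`),
  not nested within environment. For a 16 x 8 x 2 trial this gives Rep
  df 1 and Error df 127, the layout consistent with the published tables
  this package's fixtures carry.
* **"% variance"** is reported as the share of the total sum of squares,
  `100 · SS_k / SS_total`, not a REML variance-component share. The shipped
  reference table reproduces its printed shares under exactly this reading
  (67/19/13 % observed), which is how the convention was chosen.

### Stability statistics

All stability estimators operate on the genotype x environment cell means
(replicates averaged first), the convention of the underlying literature;
the full-data error mean square feeds only the significance tests inside
`kang_ysi()`.

* **Finlay–Wilkinson**: `b_i` regresses a genotype's environment means on
  the environment index `I_j = ȳ_.j − ȳ_..`; `S²d` is the deviation mean
  square on `q − 2` df. On balanced data `mean(b_i) = 1` exactly, so
  injected slopes are recoverable only when they average 1: the slopes are
  identified relative to the realized environmental gradient.
* **Wricke ecovalence** `W_i` is the genotype's share of the interaction SS
  of the cell-mean table; `ΣW_i` equals that SS to machine precision, an
  identity asserted by the oracle tests.
* **Shukla stability variance** uses the standard unbiased estimator
  `σ²_i = p·W_i/((p−2)(q−1)) − ΣW/((p−1)(p−2)(q−1))`. It is affine and
  strictly increasing in `W_i` (so the two statistics always rank
  identically) and can legitimately be negative; values are never clamped.
  A naming caution: in the published table the fixtures derive from, the
  column this estimator reproduces is the one labelled *SIGMA*; the column
  labelled *Shukla* there follows some other, unstated formula. The
  package implements the standard estimator and keeps its standard name.
* **AMMI / ASV**: the interaction residual of the cell-mean table is
  decomposed by SVD; `Σλ²` equals the interaction SS, axis scores are
  singular vectors scaled by `√λ`. The AMMI stability value follows the
  Purchase weighting `ASV_i = √((SS₁/SS₂ · IPCA1_i)² + IPCA2_i²)`; if the
  second axis is empty the package falls back to `|IPCA1|` with a warning.
* **Kang YSi** is a rank-sum: yield rank (1 = lowest), ±1 adjustment when a
  genotype mean differs from the grand mean by more than the LSD, and a
  0/−2/−4/−8 penalty by significance of `σ²_i` in an F test against the
  pooled error (`F = σ²_i · r / MS_err` on `q − 1` and error df; thresholds
  0.05/0.01/0.001 are arguments, so variants can be swapped). Genotypes
  above the mean YSi are flagged stable.
* **AICc** compares the models that define fitted cell means — additive,
  FW, AMMI1, AMMI2 — by `n·ln(RSS/n) + 2k + 2k(k+1)/(n−k−1)` with
  `n = pq`. Parameter counts are documented in `?aicc_compare`: additive
  `p+q−1`, FW adds `p−1` slopes, AMMI-m adds `m(p+q−1−m)`. A zero-RSS
  model is flagged `perfect_fit` (AICc −∞) rather than given a fabricated
  number; index-only statistics (ecovalence, σ²) define no fitted values
  and therefore no AICc. On tables too small for a model's parameter count
  (`n − k − 1 ≤ 0`), `stability_report()` simply drops that model
  (`aicc_feasible_models()`), while a direct call errors.
* Ranks use average ranks for ties with the genotype label as a stable
  second sort key; missing cells are rejected rather than imputed, because
  every estimator here assumes balance.

### Model evaluation statistics

`d_index()` follows the Willmott convention (primed deviations taken from
the *observed* mean); the reported `bias()` is signed simulated-minus-
observed, so over-prediction is positive. Both `d` and `ME` are invariant
to adding a constant to both series, which the property tests assert.

## 2. The crop simulator

The simulator is a deliberate desk-scale reduction of the CERES-Maize
process chain: rich enough to express the phenology and stress contrasts
the stability analysis needs, small enough to audit.

**Phenology.** Thermal time uses the literal clamped-mean rule above a base
of 8 °C; an optional optimum/ceiling cap (`cap = c(34, 44)`) is available
because supra-optimal temperatures otherwise keep accelerating development.
Stages: emergence at 45 °C d after sowing (a documented default; the
source material does not state one); end of juvenile phase at `P1`;
tassel initiation delayed by `P2` days per hour of day length above 12.5 h
(implemented as a fractional hold on development, so `P2 = 0` degenerates
exactly to no photoperiod effect); anthesis when all leaves have appeared
at `PHINT` °C d per tip; maturity `P5` °C d after silking. Total leaf
number is `18.6 + P1/48.2`: the two constants were fitted once, by least
squares, so that the sixteen packaged cultivars' anthesis dates under a
standard savanna temperature profile span the observed ~45–60 day range and
preserve the maturity-group ordering; they are species parameters in the
shipped YAML file, not per-cultivar tuning knobs. Days to anthesis and
maturity are reported with the fractional day at which the thermal-time
threshold is crossed, which keeps cultivar orderings free of whole-day
rounding ties.

**Growth.** Daily biomass is `RUE · PAR · (1 − e^(−KCAN·LAI)) ·
min(f_T, f_W)` with PAR = 0.5 · SRAD, RUE 4.2 g MJ⁻¹ and KCAN 0.85
(ecotype parameters). LAI rises with the fraction of appeared leaves to a
per-plant maximum of 0.55 m² and senesces linearly through grain fill.
`f_T` is the piecewise-linear PRFTC response and `f_W` the soil-water
stress factor. The energy bound `biomass ≤ RUE · Σ intercepted PAR` holds
by construction and is asserted per cultivar in the tests.

**Kernels and grain.** Kernel number is `G2 · density` multiplied by the
mean of `min(f_W, f_T)` over anthesis ± 7 days — the single shared stress
window through which drought and heat act on sink size, since the
cultivar-specific drought-tolerance ("rooting") parameter of the original
model is not published. Grain fills linearly at `G3` mg kernel⁻¹ d⁻¹
scaled by the RGFIL temperature response *and* by `f_W`; without a water
limitation on assimilate during fill, a short rainy season could never
penalise late cultivars, which is the central seasonal contrast. Grain is
additionally capped at a harvest-index ceiling (0.6) of accumulated
biomass. Under fully irrigated, high-radiation conditions the simulator
therefore expresses *potential* yields well above typical savanna field
means; all graded properties are orderings and budgets, not absolute
yields.

**Water.** A three-layer bucket: SCS curve-number runoff (CN 100 returns
all rain as runoff), saturation-excess cascade, drainage of water above the
drained upper limit at 0.4 d⁻¹, Priestley–Taylor potential ET partitioned
by canopy cover, two-stage (energy-/supply-limited) soil evaporation, and
transpiration capped at 10 % of each layer's plant-available water per
day. The stress factor is `min(1, PAW fraction / 0.5)`. The season water
balance closes exactly; the tests assert closure below 0.1 mm.

**Management.** Density defaults to 53,333 plants ha⁻¹. Sowing is either a
fixed day or moisture-triggered: the first day in the window whose
top-layer plant-available fraction reaches 0.5 (threshold 0 degenerates to
the first window day; a season that never wets up raises a classed
no-planting error). Irrigation `"auto"` refills the profile to the drained
upper limit whenever the root-zone fraction falls below 0.5 — the stated
management rule ("irrigate when below field capacity") without published
amounts, so amounts are whatever refill requires.

## 3. The synthetic generators

**Weather.** Rain occurrence is a first-order two-state chain in the Wilks
parameterisation (`p01 = (1−ρ)π`, `p11 = π + ρ(1−π)`, ρ = 0.5), whose
stationary wet-day probability `π(doy)` is a Gaussian-shaped seasonal bump;
wet-day amounts are exponential with the mean calibrated against the
discrete sum of `π` so the *expected* annual total equals the archetype
target. The dry archetype (825 mm, peak day 208, spread 27 d) concentrates
most rain in July–August; the wet archetype (1125 mm, peak 196, spread
35 d) starts earlier and spreads wider. Temperatures and radiation are
day-of-year sinusoids plus bounded uniform noise; the noise bound is
smaller than the seasonal Tmax−Tmin gap, so `Tmax > Tmin` holds on every
generated day, and wet days are slightly cooler and dimmer. Years are 365
days. Not emulated: humidity and wind, multi-day storm clustering beyond
first-order persistence, spatial correlation between sites, and trends —
so passing tests say nothing about reproducing any particular historical
record.

**Trials.** Effects are drawn, centred and rescaled exactly, and each
source's structural share is reduced by the residual-noise contribution its
SS will pick up (`df · σ²`), so every source's *expected* SS equals its
requested fraction of the total; interaction matrices are double-centred so
nothing leaks into main effects. The slope structure sets
`GE_ij = (β_i − 1) · E_j` exactly (its GEI share is then implied by `β` and
the environment share). Environment effects are drawn once per trial and
shared across replicates; the replicate effect is a crossed block. The
default seed, 20160316, is a documented constant chosen once.

**Soils.** Three texture kinds with fixed layer triplets satisfying
`LL < DUL < SAT`; sandy holds less plant-available water than loamy than
clay. These are invented parameter sets, not measured profiles.

## 4. The pipeline's "observed" arm

No field observations are published for the trials this package mirrors, so
the pipeline's observed arm is a synthetic surrogate drawn with the
variance anatomy such trials report (E 0.67, G 0.19, GEI 0.13, error 0.01
of total SS) and relabelled to match the simulated arm's genotypes and
environments. The pipeline's acceptance properties are therefore rank and
fraction properties — never value reproduction. In the default
configuration the dry-season environments are irrigated (there is no
dry-season rain to farm) and the rainy-season environments are rainfed,
which is what gives the environment term its dominant share in the
simulated arm's ANOVA.

## 5. Problem sizes used by the tests

The oracle-equivalence tests run 100 random 4x3–6x5 cell-mean tables
against explicit-loop implementations at 1e-9 relative tolerance; the
generator-recovery tests use 200 trials of 16 x 8 x 2 for variance shares
(±3 percentage points on the mean) and 20 trials for slope recovery (the
per-genotype slope estimate averaged over draws within ±0.05, the
resolution a single draw's sampling error makes meaningful); the seasonal
contrast uses 26 synthetic years per archetype for all 16 cultivars. These
sizes were chosen as the smallest that make the Monte-Carlo assertions
statistically comfortable.

## 6. Known limitations

* No nitrogen, phosphorus or potassium dynamics: the emulated trials were
  managed at optimum nutrient status, and the statistical layer never sees
  nutrients.
* No lodging, grain rots or other post-maturity losses, so late rain never
  hurts early varieties in the wet savanna — a simulated-world optimism
  that the original model shares.
* One shared stress window differentiates cultivars around anthesis;
  per-cultivar drought-tolerance parameters are not encoded because their
  values are not published.
* The simulator expresses potential-yield levels under non-stressed
  conditions; compare distributions and rankings, not absolute Mg ha⁻¹.
* All estimators require complete balanced tables; unbalanced data should
  be completed or subset upstream.
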