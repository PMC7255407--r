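# gxemaize

Genotype-by-environment interaction (GEI) and yield stability analysis for
maize multi-environment trials, paired with a desk-scale daily crop
simulator in the CERES-Maize tradition so that *simulated* yield tables can
be analysed with exactly the same statistical battery as observed ones.

## The problem

When the same maize varieties are grown across contrasting environments —
here, the dry and wet savannas of West Africa — the ranking of varieties
changes from site to site and season to season. This genotype x environment
interaction makes it hard for breeders and agronomists to recommend stable,
high-yielding varieties. Field multi-environment trials (METs) are the
standard answer but are expensive; a calibrated crop simulation model can
complement them by generating "virtual" trials for locations and seasons
where no field data exist. The question this package operationalises is:
**do simulated yields lead to the same variance partitioning and the same
stability rankings as observed yields?**

## What is inside

* **Crop simulator** (`simulate_season()`, `seasonal_analysis()`): daily
  thermal-time phenology driven by the six genotype-specific coefficients
  P1, P2, P5, G2, G3, PHINT (growing degree days above a base temperature of
  8 °C, `GDD = max(0, (Tmax + Tmin)/2 − Tbase)`), radiation-driven biomass
  `ΔW = RUE · PAR · (1 − e^(−KCAN·LAI)) · min(f_T, f_W)`, kernel set
  `G2 · density` scaled by stress around anthesis, linear grain fill at `G3`
  mg kernel⁻¹ d⁻¹, a three-layer soil water bucket with SCS curve-number
  runoff and Priestley–Taylor evapotranspiration, moisture-triggered
  planting, and an optional irrigation rule. The 16 calibrated savanna
  varieties ship as a packaged table (`maize_cultivars()`).
* **Synthetic data** (`generate_weather()`, `generate_trial()`,
  `generate_soil()`): a two-state Markov rainfall generator reproducing the
  dry-savanna (~825 mm, ~3.5-month season, >50 % of rain in July–August)
  and wet-savanna (~1125 mm, ~5-month season) regimes, plus a yield-trial
  generator `Y_ijr = μ + G_i + E_j + GE_ij + R_r + ε_ijr` whose variance
  fractions, interaction structure (multiplicative, Finlay–Wilkinson slope,
  unstructured) and seed are all controllable.
* **Model evaluation** (`d_index()`, `model_efficiency()`, `rmse()`,
  `bias()`, `evaluate_fit()`): Willmott's index of agreement
  `d = 1 − Σ(m−S)² / Σ(|S−m̄| + |m−m̄|)²`, Nash–Sutcliffe efficiency
  `ME = 1 − Σ(m−S)²/Σ(m−m̄)²`, root mean square error and signed bias.
* **GEI and stability** (`two_way_anova()`, `finlay_wilkinson()`,
  `wricke_ecovalence()`, `shukla_sigma2()`, `ammi()`, `asv()`,
  `kang_ysi()`, `aicc_compare()`, `stability_report()`,
  `rank_concordance()`): balanced ANOVA variance partitioning with %-of-SS
  shares; FW joint regression (slope `b_i`, deviation MS `S²d`); ecovalence
  `W_i = Σ_j (ȳ_ij − ȳ_i. − ȳ_.j + ȳ_..)²`; the unbiased Shukla stability
  variance `σ²_i = pW_i/((p−2)(q−1)) − ΣW/((p−1)(p−2)(q−1))`; AMMI (SVD of
  the double-centred cell means) with the AMMI stability value
  `ASV_i = √((SS₁/SS₂ · IPCA1_i)² + IPCA2_i²)`; the Kang rank-sum index;
  AICc model selection; and Spearman rank concordance between observed and
  simulated stability reports.
* **Pipeline** (`run_gxe_pipeline()`, `gxe_report()`): one call that
  simulates all cultivars over eight site x season environments (two soil
  profile pits as replicates), builds an observed-surrogate trial, and runs
  evaluation, ANOVA, stability, concordance and the 26-year seasonal
  analysis, deterministically from one seed.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods on reports, `autoplot()` for stability and seasonal
results.

## Worked example

```r
library(gxemaize)

# a 16 x 8 x 2 trial with the variance anatomy typical of savanna METs
tr <- generate_trial(trial_spec(seed = 1))
two_way_anova(tr)
#>        source  df      ss     ms  f_value p_value  pct_ss
#> 1    Genotype  15  73.551  4.903  155.840   0.000  18.908
#> 2 Environment   7 260.728 37.247 1183.779   0.000  67.028
#> 3         GEI 105  50.710  0.483   15.349   0.000  13.036
#> 4         Rep   1   0.002  0.002    0.049   0.825   0.000
#> 5       Error 127   3.996  0.031       NA      NA   1.027
#> 6       Total 255 388.986     NA       NA      NA 100.000
```

The environment explains ~67 % of the total sum of squares, genotype ~19 %
and GEI ~13 % — interaction on the same order as the genotype effect, which
is why stability statistics are needed at all.

```r
rep <- stability_report(tr)
glance(rep)
#>   pct_ss_env pct_ss_gen pct_ss_gei best_model n_stable_kang most_stable
#> 1      67.03      18.91      13.04      AMMI2             8         G03

head(dplyr::select(rep$genotypes, genotype, mean_yield, bi, sigma2, asv, ysi), 4)
#>   mean_yield    bi sigma2   asv ysi
#> 1      3.382 0.951  0.123 0.737  -5
#> 2      3.856 0.959  0.062 0.507   0
#> 3      3.322 1.039  0.005 0.249   2
#> 4      4.608 0.945  0.631 1.870   9
```

Per genotype: the mean yield (Mg ha⁻¹), the FW sensitivity slope (`bi`
near 1 = average response), the Shukla stability variance (`sigma2`, lower
= more stable; may be negative — it is an unbiased estimator), the AMMI
stability value and the Kang rank-sum score (higher = better joint
yield-stability standing).

Applying the Shukla estimator to a published set of 16 ecovalences
(p = 16, q = 8):

```r
eco <- readr::read_csv(system.file("extdata", "ecovalence_table7.csv",
                                   package = "gxemaize"))
shukla_sigma2(eco$ecovalence_obs, 16, 8)[eco$genotype == "IWDC2"]
#> [1] 1147.4
```

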