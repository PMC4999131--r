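# agroclim

Data-driven agronomy for rice: link daily weather series to harvest
records, find the growth-stage climatic factors that limit yield with
conditional inference forests, and classify cropping seasons by their
full daily weather patterns with dynamic-time-warping clustering.

The package is written for agronomists and biostatisticians who hold two
mundane but powerful data sources — commercial harvest records
(locality, cultivar, sowing/harvest date, yield) and nearby weather
stations — and want explanatory, not predictive, answers: *which*
climatic conditions, in *which* growth stage, limited yield, and *what*
did past seasons with similar weather deliver.

## What it implements

**Weather preparation.** Station screening (< 10 km, ±50 m altitude),
strict >80 % hourly-to-daily aggregation, WMO-style quality control,
Angstrom–Prescott solar radiation from sunshine duration with FAO-56
extraterrestrial radiation, primary-first station merging, gap filling
of TX/TM/P by an anomaly VAR(1) conditional-expectation filler and of
RH/SR by a regression random forest (ntree = 800, mtry = 2), and
derivation of mean temperature TA = (TX+TM)/2 and diurnal range
DR = TX − TM.

**Cropping events and indicators.** Each harvest record is joined to its
sowing→harvest daily weather window; missing sowing dates are estimated
by locality-typical cycle lengths (126/128 days). Cultivar stage
profiles (VEG/REP/RIP on a 126-day reference) are scaled proportionally
with largest-remainder rounding, and the standard 27 stage indicators
are computed (stage means of TX/TM/TA/DR/RH, stage heat-exceedance
frequencies above 35/37/31 °C, accumulated P and SR, frequency of
> 10 mm rain days).

**Variable importance.** A conditional inference regression forest
(association-test split selection with Bonferroni stopping, ntree = 2000,
mtry = p/3 by default) with *conditional* permutation importance:
predictors are permuted within the strata their correlated covariates
induce in each tree, so proxies do not inherit their correlates' credit.
Ensembles of runs (100 by default; 100 subsets × 400 rows when
n > 500) are aggregated as normalized, OOB-R²-scaled importances,
letter-grouped by Kruskal–Wallis rank comparisons, and read through
partial dependence profiles with breakpoint estimation.

For a predictor x with importance VI_r in run r with performance R²_r:

    final_VI(x) = mean_r [ VI_r(x) / Σ_x VI_r(x) · R²_r ]

**Pattern clustering.** Events are compared by the sum over the five
climatic variables of univariate DTW distances between their pooled
z-scored daily series, clustered with Ward (Lance–Williams on squared
distances), the cluster count selected by relative inertia gain, and
per-cluster yield and cultivar differences letter-grouped (clusters with
fewer than ten events are not considered for cultivar comparisons).

**Synthetic truth.** A seasonal-harmonic + AR(1) + Markov-gamma weather
generator, cropping-event sampler, and a configurable yield response
(cultivar effects; linear/hinge/saturating drivers; noise calibrated to
a target population R²) provide ground truth for every validation in the
test suite, including a two-regime mixture generator for clustering
recovery.

## Worked example

```r
library(agroclim)

## 600 synthetic cropping events whose yields carry two known drivers:
## a -600 kg/ha/degC hinge on reproductive-stage minimum temperature
## above 22.7 degC and +0.29 kg/ha per cal/cm2 of ripening-stage solar
## energy, noise calibrated to a population R2 of 0.35
sim <- simulate_indicator_dataset(n_events = 600, target_r2 = 0.35, seed = 1)

vi <- vi_ensemble(sim$indicators, control = cif_control(ntree = 200),
                  runs = 20, subsets = 20, seed = 2)
print(vi, n = 5)
#> Variable-importance ensemble: 20 runs (subsampled protocol), mean R2 = 0.246 (sd 0.026)
#>               final_VI letters
#> SR_Accu_RIP    0.08743       a
#> TM_Avg_REP     0.03406      ab
#> Cultivar       0.03343      ab
#> P_Accu_RIP     0.01184      bc
#> P_10_Freq_RIP  0.01145      bc
```

Both planted drivers surface at the top of the importance ranking (with
the planted cultivar effects beside them), and the ensemble's mean
out-of-bag R² of 0.25 sits near the 0.35 population ceiling that the
noise calibration imposed — an honest gap, since forests do not fully
capture a hinge from 600 noisy events. The letters say SR_Accu_RIP's
importance distribution is significantly above the pack ("a"), while
TM_Avg_REP and Cultivar share its group boundary ("ab").

The fitted response shape is read from partial dependence (here on a
strong-signal variant, `target_r2 = 0.7`, where the breakpoint is
identifiable):

```r
sim2 <- simulate_indicator_dataset(n_events = 600, target_r2 = 0.7, seed = 1)
fit <- cif_forest(sim2$indicators[setdiff(names(sim2$indicators),
                                          c("event_id", "Yield"))],
                  sim2$indicators$Yield, cif_control(ntree = 200), seed = 4)
pd <- partial_dependence(fit, "TM_Avg_REP")
pd_breakpoint(pd)
#> [1] 23.68
```

The maximum-curvature estimate lands within a degree of the planted
22.7 °C hinge. Weather-pattern clustering recovers known regimes:

```r
mix <- generate_regime_mixture(k = 2, events_per_regime = 40, seed = 3)
cl <- weather_pattern_clusters(mix$bundles)
print(cl)
#> Weather-pattern clustering: 80 events in 2 clusters
#> cluster
#>  1  2
#> 40 40
```

`cmd_simulate()` and `cmd_run_all()` run the whole chain from a single
`pipeline_config()` and write CSV/JSON reports plus a manifest, and the
same functions accept prepared real data through `standardize_records()`,
`prepare_weather()` and `build_indicator_table()`.

## Vignette

`vignettes/agroclim-methods.Rmd` documents the models and their
assumptions: the QC and imputation choices, the tree-growing and
conditional-permutation algorithms, the ensemble aggregation and letter
procedure, the DTW/Ward/inertia-gain choices, what the synthetic
generator does and does not emulate, and known limitations.
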