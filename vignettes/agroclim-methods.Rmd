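---
title: "Methods: agro-climatic indicators, forest-based variable importance and weather-pattern clustering"
author: "agroclim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agro-climatic indicators, forest-based variable importance and weather-pattern clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Commercial harvest records — locality, cultivar, sowing and harvest date,
yield — accumulate by the thousands in rice-growing regions, and daily
weather stations sit nearby. `agroclim` implements an observational
analysis chain that links the two: it prepares complete daily weather
series per locality, joins each harvest record to the weather its crop
actually experienced (a *cropping event*), condenses each event into
growth-stage climatic indicators, asks a conditional inference forest
which indicators limit yield, and independently groups events by their
whole daily weather patterns to compare the yields achieved under each
pattern. Because real agronomic census data are rarely redistributable,
the package carries a synthetic generator with known ground truth so that
every stage of the chain can be validated end to end.

```{r, eval = FALSE}
library(agroclim)
sim <- simulate_indicator_dataset(n_events = 600, target_r2 = 0.35, seed = 1)
vi  <- vi_ensemble(sim$indicators, control = cif_control(ntree = 200),
                   runs = 20, subsets = 20, seed = 2)
print(vi)
```

## Weather preparation

Station records enter as daily (or hourly) series of maximum temperature
(TX), minimum temperature (TM), precipitation (P), relative humidity (RH)
and solar radiation (SR).

* **Station screening** (`select_stations()`): stations within 10 km
  great-circle distance of the fields and within ±50 m altitude,
  nearest first. Distances come from the haversine formula
  (`geosphere`).
* **Hourly aggregation** (`aggregate_hourly_to_daily()`): a day is
  computed only when *strictly more than* 80 % of its 24 hourly values
  are valid — 19 valid hours (79 %) leaves the day missing, 20 makes it
  present. The threshold is configurable; strictness is deliberate and
  documented here because the rounding direction changes boundary days.
* **Quality control** (`qc_daily()`): WMO-style plausibility screening.
  The guideline texts give no numeric limits, so the defaults
  (TX ∈ [10, 45] °C, TM ∈ [5, 35] °C, P ∈ [0, 300] mm, RH ∈ [0, 100] %,
  SR ∈ (0, 900] cal cm⁻²) are tropical-plausible and fully configurable;
  TM > TX days flag both values, and runs of ≥ 5 identical
  temperature/humidity values flag a stuck sensor. QC flags and sets to
  missing; it never aborts.
* **Radiation from sunshine** (`solar_from_sunshine()`): the
  Angstrom–Prescott relation SR = (a + b·n/N)·Ra with the FAO-56
  recommended a = 0.25, b = 0.50 (used when no local calibration
  exists), N from the sunset hour angle and Ra from the FAO-56
  extraterrestrial-radiation formulation. SR is stored in
  cal cm⁻² day⁻¹ throughout; the single conversion constant is
  1 MJ m⁻² = 23.884 cal cm⁻².
* **Station merging** (`merge_station_series()`): primary-first cell
  merge for stations with complementary recording periods, with
  per-cell provenance and a conflict log (disagreements > 2 °C for
  temperature, > 20 % for precipitation).
* **Gap filling**: TX/TM/P gaps are filled by an anomaly VAR(1) — each
  series deseasonalized against a circularly smoothed day-of-year
  climatology (precipitation on a log1p scale), a first-order vector
  autoregression fitted by least squares on complete consecutive-day
  pairs (at least 60 required), and gaps replaced by the Gaussian
  conditional expectation given the same-day observed variables and both
  temporal neighbours (forward and backward passes, averaged). The
  deterministic conditional-mean fill is the default; stochastic fill
  adds seeded conditional noise. This is a transparent, self-contained
  weather-generator-style imputer, not a reimplementation of any
  specific calibrated generator. Filled precipitation below 0.1 mm is
  snapped to zero to preserve dry days. RH and SR gaps are filled by a
  regression random forest (`randomForest`, ntree = 800, mtry = 2) on
  TX, TM and P; filled RH is clipped to [0, 100] and SR floored at a
  small positive value. Imputation never alters an observed cell, and
  the imputed mask marks exactly the originally missing cells. If a
  filled day inverts TM/TX the pair is swapped and flagged rather than
  dropped, keeping the series complete.
* **Derived temperatures** (`derive_ta_dr()`): TA = (TX + TM)/2 and
  DR = TX − TM. An alternative printed convention defines TA as half the
  diurnal range; since a quantity called *average temperature* must lie
  between TM and TX for the stage indicators to make sense, the mean
  form is the default and `ta_formula = "paper_literal"` reproduces the
  other reading for cross-checks.

## Cropping events and stage indicators

A cropping event is one harvest record joined to its sowing-to-harvest
daily weather window (both endpoints included, so a 126-day cycle spans
127 rows). Missing sowing dates are estimated by subtracting the
locality's typical cycle length from the harvest date (126 days and
128 days for the two default localities; configurable per locality).

Each cultivar has expert-defined reference stage durations — vegetative
(VEG, germination to panicle-primordia initiation), reproductive (REP, to
heading), ripening (RIP, to maturity) — on a 126-day reference cycle.
Real profiles are configuration, not constants; the shipped defaults
(e.g. 55/36/35) are synthetic stand-ins. For an actual cycle the
durations are scaled proportionally and rounded by largest remainder so
the three stage lengths sum exactly to the cycle length. Stage
membership uses half-open date intervals [start, next start): every day
belongs to exactly one stage, and the harvest day itself — the closing
endpoint — belongs to none.

`compute_stage_indicators()` produces the standard 27 predictors: per
stage, means of TX, TM, TA, DR and RH; accumulated P and SR; the
frequency of days with TX strictly above the stage threshold (35 °C in
VEG, 37 °C in REP, 31 °C in RIP — anthesis sterility and ripening
thresholds); and the frequency of days with strictly more than 10 mm
precipitation. Frequencies are proportions of stage days, hence
unitless in [0, 1]. Exceedance is strict ("above").

`clean_indicator_table()` removes predictors with near-zero variability
(absolute sd < 1e−8, or coefficient of variation < 0.01 — configurable)
and rows whose yield or any predictor falls outside median ± 3·IQR per
locality. No outlier rule is canonical for these data; the median/IQR
fence was chosen as a conservative, distribution-free default, and a
variable whose IQR is zero (half its values identical) contributes no
fence rather than flagging every non-median value.

## Conditional inference forests and variable importance

The explanatory engine is a regression forest of conditional-inference
trees, written in compiled code in this package:

* each tree grows on a bootstrap sample; the out-of-bag (OOB) indices
  are retained;
* at each node, `mtry` candidate predictors are drawn without
  replacement and the candidate with the smallest p-value of a
  standardized linear association statistic (permutation variance;
  categorical predictors via the maximum over level-indicator
  statistics with a Bonferroni correction over levels) is selected;
* the node does not split when the Bonferroni-adjusted minimum p-value
  exceeds `alpha_split` (default 0.05) or the node is smaller than
  `minsplit` (20); the split point maximizes the standardized
  two-sample statistic subject to `minbucket` (7);
* predictions average terminal-node means over trees.

Defaults are ntree = 2000 and mtry = round(p/3) (9 for the 27-indicator
table), the configuration customary for maximizing the discriminating
power of such models on indicator tables. Everything is deterministic
given a seed.

**Importance.** Permutation importance measures the increase in OOB mean
squared error when a predictor's values are shuffled. The *conditional*
variant shuffles within the cells of the partition induced by the tree's
own split points on the covariates whose absolute Spearman correlation
with the permuted predictor exceeds 0.2 — this isolates a predictor's
own contribution from what it merely shares with correlates, the
property that makes the method suitable for identifying limiting factors
rather than mere proxies. Only numeric covariates enter conditioning
sets (rank correlation with an unordered cultivar factor is undefined);
the cultivar column can itself be permuted and split on. Negative
importances (Monte-Carlo noise around zero) are retained.

**Ensembles.** One forest is an unstable rankings source, so
`vi_ensemble()` trains many (100 by default): each run's raw importance
vector is normalized by its sum, scaled by that run's OOB R² (so
well-adjusted models weigh more), and the final importance is the
per-predictor mean over runs. Whether "the model's performance" should
be in-sample or OOB R² is ambiguous in common usage; OOB is used here to
avoid optimism. A run whose raw importances nearly cancel — sum
non-positive, or smaller than the largest single magnitude — is
*degenerate*: dividing by such a sum no longer reads as a share of total
importance (shares would exceed 1 and explode), so the run receives the
uniform vector and a flag. Tables larger than 500 rows switch to the
subsampling protocol: 100 independently drawn subsets of 400 distinct
rows, one forest per subset, aggregated identically. Per-cultivar models
(`per_cultivar_vi()`) run on cultivars with strictly more than 100
observations, excluding the cultivar column.

Per-predictor importance distributions over runs are compared by a
Kruskal–Wallis omnibus test followed by pairwise mean-rank
normal-approximation comparisons at the 5 % level (midranks and tie
correction; uncorrected by default, matching the customary agronomic
letter display, with a Bonferroni option) and compact letters assigned
by insert-and-absorb. `partial_dependence()` traces a predictor's
partial relation to yield by forcing it across a 1st–99th percentile
quantile grid and averaging forest predictions; `pd_breakpoint()`
locates the maximum-curvature point of the profile, used to read off
response thresholds such as the night-temperature hinge.

## Weather-pattern clustering

Instead of summarizing events into indicators, the second analysis path
compares events by their *entire* multivariate daily weather pattern,
preserving short heat and drought spells that stage averages smooth
away. The five raw daily series are pooled-z-scored per variable (so
millimetres and calories are commensurate), and the distance between two
events is the equal-weight sum over variables of univariate dynamic time
warping distances (absolute-difference local cost, symmetric
match/insert/delete steps, boundary-anchored, no window) — the
"independent" multivariate DTW, which tolerates events of different
cycle lengths. How to combine five series into one elastic distance is a
genuine design choice; per-variable DTW with configurable weights was
chosen for transparency, and series are compared raw (unsmoothed) to
honour day-to-day variability.

Events are clustered agglomeratively with Ward-style Lance–Williams
updates on squared distances, so merge heights track within-cluster
inertia (average and complete linkage are selectable; the implementation
is cross-checked against `stats::hclust` in the tests). The number of
clusters maximizes the *relative inertia gain* gain(k)/W(k), where
gain(k) is the height of the merge collapsing k clusters into k − 1 and
W(k) the inertia remaining below that cut. Normalizing by the remaining
inertia rather than by the next single gain keeps the elbow stable deep
in the tree, where individual merge heights are tiny and their pairwise
ratios are noise; the criterion is invariant to uniform scaling of all
distances, and a flat dendrogram falls back to `k_min` with a warning.

Per-cluster yields are summarized and letter-grouped with the same
Kruskal–Wallis machinery; clusters of fewer than ten events are not
considered for the within-cluster cultivar comparison, and within a
cluster, cultivars with fewer than five observations (a package choice)
are pooled out of the test.

## The synthetic generator

The generator is a minimal structural emulator — enough realism to
exercise every analysis stage, no claim of climatological fidelity:

* TX = annual harmonic + AR(1) anomaly (default amplitude 2 °C around
  32 °C, lag-1 coefficient 0.7);
* the diurnal range DR has its own harmonic (amplitude 1.5 °C around
  9 °C) and its own persistent AR(1) anomaly emulating cloud-cover
  persistence, and TM = TX − DR with DR floored above zero. Giving DR
  independent structure matters: without it TM is an affine copy of TX
  and every temperature indicator collapses into one collinear block,
  which no importance method could disentangle — real tropical
  minimum temperatures vary far less, and far more independently, than
  maxima (observed coefficients of variation of roughly 0.04 vs 0.07);
* precipitation follows a seasonally modulated two-state wet/dry Markov
  chain with gamma amounts; the default is the bimodal (two wet
  seasons) annual cycle of the reference region;
* RH is inversely coupled to the diurnal range with a wet-day bump,
  clipped to [0, 100]; SR is a clear-sky value attenuated on wet days
  and floored positive.

Defaults keep the marginal ranges inside the observed-variability
envelope of the motivating region (daily TX roughly 23–40 °C, TM
18–27 °C centred near 23 °C). One master seed is split deterministically
into per-variable streams, so adding a variable never perturbs earlier
draws, and identical seeds give bit-identical series.

Yields follow a known response: base 2,300 kg ha⁻¹, additive cultivar
effects (±300), a hinge of −600 kg ha⁻¹ °C⁻¹ on reproductive-stage
minimum temperature above 22.7 °C, and +0.29 kg ha⁻¹ per cal cm⁻² of
ripening-stage accumulated radiation, plus Gaussian noise, truncated
below at 500 kg ha⁻¹. The radiation coefficient is the classic
controlled-environment sensitivity (≈ 1,000 kg ha⁻¹ per
100 cal cm⁻² day⁻¹ sustained over a 35-day ripening stage); the hinge
coefficient is sized so the night-temperature and radiation terms
contribute variance of the same order, mirroring field findings in
which both rank among the top limiting factors; the base puts mean
yields near the typical irrigated average (≈ 6,100 kg ha⁻¹).
`calibrate_noise_sd()` sets the residual standard deviation so the
population R² equals a target (0.35 by default, inside the 28–47 % range
typical of such observational models). What the generator does *not*
emulate — interannual climate modes, spatial station error, pests,
management trends — bounds what passing tests can claim: they validate
the analysis machinery, not regional climatology.

## Validation design and problem sizes

The test suite validates each stage against independent oracles:
exhaustive warping-path enumeration for DTW (series of length ≤ 6),
brute-force daily loops for indicators and hourly aggregation,
`stats::hclust` for the Lance–Williams merges, hand haversine distances,
published FAO-56 worked values for extraterrestrial radiation, and
direct pairwise rank tests for the letter groups. End-to-end checks run
replicate pipelines at a reduced analysis configuration — 600-event
tables, forests of 200 trees, 20-run ensembles, 10 replicate pipelines
per scenario, 10 clustering seeds — sizes chosen to keep the full suite
in the low minutes on a single core while leaving the per-criterion
thresholds (driver recovery in the top 3, ensemble R² bands, ARI ≥ 0.9,
breakpoint within ±1 °C) at full strength. `scripts/acceptance.R` reruns
the same quantities from scratch for any seed.

## Numerical choices, degenerate inputs and limitations

* Split search uses midpoint thresholds between consecutive distinct
  values; ties in the association statistic resolve to the first
  candidate drawn, which keeps fits deterministic under a seed.
* A constant response, missing predictor values, or a factor with more
  than 32 levels are rejected at fit time with explicit messages;
  constant predictors are rejected by `partial_dependence()`.
* OOB R² may be negative and is not clipped; observations never OOB are
  excluded from the score.
* The VAR imputer requires 60 complete consecutive-day pairs and fails
  loudly below that; the forest imputer requires 100 complete training
  days and leaves gaps whose predictors are missing, reporting them.
* DTW distances are sums of per-variable path costs, not metrics in the
  triangle-inequality sense; the clustering machinery never assumes
  metricity.
* Letter displays use uncorrected pairwise comparisons at 5 % by
  convention; with many items this inflates pairwise error — the
  Bonferroni option exists for conservative reporting.
* The package analyzes whatever events it is given as one pool;
  it deliberately implements no phenology model (stage splits are
  calendar-proportional, not thermal-time) and no biotic-stress
  adjustment, and cluster counts and yield levels on real data are
  data-dependent outcomes, not package constants.
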