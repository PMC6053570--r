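---
title: "Modelling untargeted foliar metabolomes from field-sampled plant populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling untargeted foliar metabolomes from field-sampled plant populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Untargeted LC-MS profiling of leaves collected *in situ* produces a wide
table of feature intensities — one column per deconvoluted mass-spectral
signal, identified by retention time and m/z (`"2.41_343.82"` is the feature
eluting at 2.41 min with mass 343.82 Da) — together with sample metadata
describing a hierarchical field design: populations sampled across
geographic regions, a few plants per population, and within each plant a
paired contrast of one herbivore-damaged and one undamaged leaf, each
injected in triplicate alongside pooled quality-control (QC) injections.

Three properties of such data shape the whole pipeline:

1. **Technical structure.** Feature intensities are arbitrary counts whose
   per-sample totals drift with injection; many features are irreproducible
   across repeated injections of the same pooled material.
2. **Zero inflation.** A large fraction of observations are exact zeros —
   the feature is absent from that leaf or below the detection limit — so
   neither a normal nor a log-normal model fits the raw responses.
3. **Hierarchical, unbalanced design.** Leaves are nested in plants in
   populations, and the explanatory variables of interest vary at different
   levels: region, habitat, light, and geographic distance vary between
   populations; soil pH and phenology between plants; leaf area and damage
   between leaves.

`folmet` implements the full analysis chain: preprocessing, spatial
predictor construction, ordination and variation partitioning, a per-feature
conditional log-normal (two-part hurdle) model with FDR control and Tukey
post hoc contrasts, a Spearman co-occurrence network, and a targeted screen
of known standards — plus a synthetic-study generator with planted ground
truth against which every stage is validated.

## Preprocessing

Stages run in a fixed order: **normalize → QC filter → average replicates**
(with paired differencing available downstream).

* `normalize_total_intensity()` rescales every injection so its summed
  feature intensity equals a common target (default 10,000 — the constant is
  arbitrary because all downstream statistics are scale-free or per-feature;
  it is exposed as a parameter).
* `qc_rsd_filter()` computes, per feature, the relative standard deviation
  (RSD = 100·sd/mean, with the sample *n−1* standard deviation) across the
  pooled-QC injections and removes features above a threshold (default 30%,
  the conventional repeatability bound for untargeted biomarker data).
  Features whose QC mean is zero have an undefined RSD and are treated as
  failing. The RSD is computed on normalized intensities; whether filtering
  should precede or follow normalization is genuinely ambiguous in practice,
  so the order is fixed, documented, and trivially changed by composing the
  two functions the other way.
* `average_replicates()` collapses the triplicate injections of each leaf to
  their arithmetic mean, leaving one row per leaf. Because zeros propagate
  through the mean, the hurdle structure (exact zeros vs positive
  intensities) survives averaging.
* `paired_difference()` reduces the paired-leaf design to one row per plant
  (undamaged minus damaged, M~U~ − M~D~), removing all plant-level variation;
  this is the input for the leaf-area/damage variation-partitioning model.

## Spatial predictors

`euclidean_distance()` treats latitude/longitude as planar decimal degrees,
matching the common (if crude) practice for within-country extents; a
`project` option rescales longitude by cos(mean latitude) when
kilometre-faithful ratios matter. `pcnm_axes()` builds spatial eigenvectors
(PCNM): distances beyond a truncation threshold — by default the longest
edge of the minimum spanning tree, the smallest value keeping the site
network connected — are replaced by four times the threshold; the matrix
−D²/2 is double-centred and eigendecomposed; axes with positive eigenvalues
are kept, scaled by the square root of their eigenvalue, and sign-fixed so
the first nonzero score of each axis is positive (eigenvector signs are
arbitrary). The first two axes serve as the "geographic distance" predictors
in the per-feature models, the conventional broad-scale choice; the number
is configurable.

## Ordination and variation partitioning

`bray_curtis()` and `nmds()` provide the standard community-style
visualization: Kruskal stress-1 minimized by monotone-regression descent
(vegan's engine underneath), best of one principal-coordinate start plus 20
random restarts, final configuration centred and rotated to principal axes.
The stress trace of the winning restart is recorded so monotone descent is
testable rather than assumed.

`redundancy_rsq()` computes the multivariate R² of the column-centred
feature matrix on an encoded predictor block by direct least squares, with
the Ezekiel adjustment `1 − (1 − R²)(n − 1)/(n − p − 1)`. Categorical
predictors use treatment contrasts with the alphabetically first level as
reference — the choice affects nothing downstream except coefficient
labels, since R² depends only on the column space. `varpart_blocks()`
evaluates the adjusted R² of every union of 2–3 blocks and solves the
inclusion–exclusion system exactly (a 7×7 linear solve in the 3-block case)
for unique and shared fractions; adjusted fractions may legitimately be
slightly negative. Marginal per-block significance uses a permutation F test
(`permutation_f_test()`): rows of the response are permuted, and
`p = (1 + #{F* ≥ F}) / (1 + n_perm)` — the +1 correction keeps p away from
zero. The default inputs follow the design's repeated-measures logic:
per-plant means (n = 45) for the soil/region/phenology model and the
paired-difference table (n = 45) for the leaf-area/damage model, so no
pseudo-replication of leaves enters either model.

## The conditional log-normal model

Each feature is analysed separately for each explanatory variable. Writing
`y_i` for a feature's averaged intensity in leaf `i`:

* **Binary part.** `Z_i = 1{y_i > 0}` follows a logistic regression on the
  factor of interest plus the standing covariates, with a population random
  intercept where estimable. The fallback ladder is: random-intercept
  logistic (Laplace fit) → fixed population effects (only when not aliased
  with the factor — for region the population factor is perfectly aliased,
  so this rung is skipped) → plain logistic. Complete separation (any
  |coefficient| beyond 15 on the logit scale, a scale at which fitted
  probabilities are numerically 0/1) drops the binary contribution with a
  flag rather than reporting a spurious likelihood.
* **Positive part.** `log(y_i) | y_i > 0` follows a linear mixed model with
  plant-within-population random intercepts.
* **Covariates.** All analyses adjust for log leaf area and soil pH on a
  quadratic scale (centred pH and its square), except when the factor of
  interest *is* one of those, in which case it is excluded from the
  covariate set. Soil EC and C:N correlate strongly with pH, so pH alone
  represents the edaphic axis.
* **Eligibility.** A feature enters an analysis only if it has at least 5
  positive observations overall and, for categorical factors, at least 2
  positives in every level; all-zero features are never tested and
  all-positive features are tested by the positive part alone. These
  thresholds reproduce the realistic situation in which each factor tests a
  slightly different feature count.

### Combining the two parts

Because presence and positive intensity are modelled separately, each part
yields its own test of the factor, and the two must be combined. Two rules
are implemented (`cln_spec(method = ...)`):

* `"f_fisher"` (default): the positive part is a REML fit tested with a
  *joint Satterthwaite F* across the factor's coefficients; the binary part
  is tested by its likelihood-ratio chi-square; the two p-values are
  combined by Fisher's method (−2Σlog p ~ χ² with 2k df).
* `"lr_additive"`: both parts are maximum-likelihood fits compared against
  factor-free reductions; the factorized likelihood makes log-likelihood
  differences and degrees of freedom additive across parts, and the summed
  statistic is referred to a chi-square (`combined_lr_test()`).

The additive chi-square is the textbook construction, but it is
anticonservative under exactly this design: a between-population factor
tested over 15 populations with ML-estimated variance components has far
fewer effective denominator degrees of freedom than the chi-square assumes.
On null synthetic studies at the default design the additive rule rejects
roughly twice the nominal 5% rate, while the Satterthwaite F tracks the
effective df and is close to nominal — hence the default.

One further safeguard matters at this scale. With 15 populations, REML
frequently estimates the population variance at the zero boundary for
individual features; for those features the Satterthwaite denominator df
balloons toward the leaf-level residual df and the test becomes liberal
precisely where it is most dangerous. The classical between-within
(containment) rule caps the denominator df at the stratum where the factor
varies: population-level factors (region, distance, habitat, light) are
tested against at most `n_populations − df − 1` denominator df, plant-level
factors (soil pH, phenology) against at most
`n_plants − n_populations − df`, and leaf-level factors (leaf status, leaf
area) are left to Satterthwaite. The cap only binds when the boundary
problem occurs; otherwise the Satterthwaite value (typically near the
containment value anyway) is used. The result is slightly conservative in
the bulk — appropriate for a screening method whose discoveries feed
post hoc interpretation.

### Multiplicity and post hoc contrasts

Per factor, p-values over eligible features are converted to q-values by
Benjamini–Hochberg step-up (`fdr_bh()`, with m equal to the number of
*tested* features); q < 0.20 is the reporting threshold, with 0.10/0.05
tiers and raw p tallies also reported (`significance_tallies()`). Features
significant for a categorical factor get all pairwise level contrasts on the
positive-part model scale with studentized-range (Tukey) adjustment
(`tukey_posthoc()`, asymptotic df); with two levels the adjusted p equals
the unadjusted contrast p. Running the contrasts on the positive part only
is a choice: the binary part rarely carries level-specific information once
a feature passes eligibility, and a contrast on the log-intensity scale has
a direct fold-change interpretation.

## Co-occurrence network

Features significant for region (any list is accepted) are correlated
pairwise by Spearman rank correlation over all averaged leaves. An
undirected edge joins feature pairs with ρ at or above a threshold — default
0.372, the conventional value equated with p < 0.01 (and indeed
`critical_rho(47, 0.01)` ≈ 0.372; the function recomputes the threshold for
any n, by exhaustive permutation enumeration for n ≤ 8 and by inverting the
t approximation otherwise). Only positive correlations count as
co-occurrence. Connected components label putative regional fingerprints,
and each node carries its mean normalized abundance per region (the
pie-chart fractions of the usual network figure). Isolated nodes are
retained in the graph but carry no co-occurrence evidence; cluster-recovery
scoring in the test suite therefore evaluates the partition over
non-isolated nodes (under the default planted magnitudes a few weakly
present features never reach the threshold against any sibling, which
fragments a singleton-inclusive score even when the recovered blocks are
perfectly pure).

## Targeted screen

`match_targets()` matches known standards to unfiltered features by
retention-time and mass windows (defaults 0.20 min and 0.05 Da — the same
tolerances as upstream peak alignment, adopted because screening windows are
rarely reported); all matches are reported ranked by combined normalized
distance, and downstream tests use the closest. `screen_targets()` compares
damaged vs undamaged per-leaf intensities per compound with a two-sided
Mann–Whitney U test (exact for two small tie-free groups), unpaired by
default to mirror common practice; a within-plant paired signed-rank option
exists because the design is paired.

## The synthetic-study generator

`generate_study()` draws a complete study whose *defaults are the emulated
design*: 15 named populations in 3 regions (3/6/6 split), 3 plants per
population, one undamaged and one damaged leaf per plant, triplicate
injections (270 biological rows), 48 usable pooled-QC injections plus 8
column-conditioning injections, and 541 features of which 344 are planted
QC-RSD violators so the 30% filter retains 197. Planted effect sets are
sized like the outcome they emulate: 30 region features (three disjoint
blocks of 10, each elevated by a log-fold shift of 2 in one region), 8 soil
pH features (linear + concave quadratic on centred pH), 4 habitat features
(elevated in forest), 3 leaf-area features (slope on centred log area).

The intensity model is the same two-part structure the analysis assumes:
per-leaf presence `Z ~ Bernoulli(π_f)` with per-feature prevalence drawn
from a common range (0.65–0.98) plus a low-prevalence tail (12% of features
at 0.10–0.35, which is what makes eligibility counts realistic), and
`log`-scale intensity `η + ε` with feature baselines ~ N(4, 1), population
and plant random intercepts (SD 0.3 each), leaf-level residual SD 0.5, and
mean-one log-normal injection noise at 10% CV (80% CV for planted
violators, applied to both biological and QC injections). QC rows are the
pooled mean of all leaves times the same per-feature noise. Soil pH has
region-specific means (5.5/6.4/6.7, SD 0.6 — sandier, more acidic western
soils) and EC and C:N are generated as monotone transforms of a latent that
is orthogonalized against the pH normal scores in-sample, pinning their
Spearman correlations with pH at the configured targets (0.49 and 0.39)
rather than only in expectation. Values the emulated design does not pin
down (variances, prevalences, CVs, leaf-area and damage distributions) were
chosen once as field-realistic magnitudes and are all exposed in
`sim_config()`.

Planted effects enter the positive (log-intensity) part only; presence
probabilities are effect-free. This matches what a log-fold effect
magnitude means and keeps the two parts' roles separable in validation;
binary-part effects can be emulated by adjusting `pi_*` ranges per group if
needed.

What the generator does **not** emulate: chromatographic drift and
retention-time shifts between batches, correlated features (adducts and
fragments of one metabolite), detection-limit censoring that depends on
abundance (zeros are missing-at-random given π), spatially autocorrelated
environments beyond the region means, and genotype structure. Passing tests
therefore demonstrate that the statistics do what they claim under a
faithful hierarchical zero-inflated log-normal world — not that any
particular biological conclusion from real data is correct.

## Numerical choices and degenerate inputs

* All seeds are explicit; pipeline stages derive per-stage seeds by hashing
  the stage name with the master seed, so any stage reproduces in isolation.
* Likelihood-ratio statistics that come out marginally negative (optimizer
  noise) are clamped to zero; beyond 1e−6 they are flagged (`negative_lr`).
* Fisher combination floors p-values at 1e−300 before taking logs.
* A perfect multivariate fit (R² numerically ≥ 1) is clamped so permutation
  F tests return `p = 1/(1 + n_perm)` rather than NaN.
* Feature-id text is preserved verbatim on read; generated ids use 4
  decimals (trailing zeros dropped), and parsing round-trips exactly for
  inputs at that precision.
* Constant features yield `NA` Spearman correlations and no edges; all-zero
  samples are rejected at normalization; coincident sites give a "no
  positive axes" error from PCNM.

## Problem sizes in the test suite

The suite validates filtering exactness over 100 generated studies at the
full default design; FDR control over 20 null studies (analysing region per
study, ~190 eligible features each); effect recovery and pH-coefficient
signs over 5 replicate studies; variation-partitioning recovery at n = 500
with planted 5%/8% variance shares; and the small-instance oracles
(Bray–Curtis, BH, Mann–Whitney, Spearman, PCNM, adjusted R²) against
brute-force computations at 1e−8. These sizes keep the default `testthat`
run to roughly ten minutes on one core while leaving every statistical
claim backed by a planted-truth or brute-force comparison.

## Known limitations

* Per-feature mixed models at 15 populations remain delicate; the
  containment bound trades a little power for calibration, and features
  whose positive part falls back to plain least squares (too few positives
  per plant) lose the population-level error stratum in the positive part
  (the bound still caps their denominator df).
* The additive-LR combination is retained for comparability but is not
  calibrated at this design size; its p-values should not be taken at face
  value below ~0.01.
* Fisher's combination assumes the two parts are independent, which holds
  under the hurdle factorization but would be violated by
  abundance-dependent censoring.
* The network threshold convention (0.372 ↔ p < 0.01) depends on an
  unstated sample count (≈47); the constant is therefore an override with
  `critical_rho()` available when the actual n should govern.

## A minimal session

```{r example}
library(folmet)

study <- generate_study(sim_config(), seed = 1)
targets <- demo_targets(study)
report <- run_pipeline(study, pipeline_config(seed = 1), targets = targets)
print(report)

## or stage by stage
md <- study$metadata
norm <- normalize_total_intensity(study$table)
filt <- qc_rsd_filter(norm, md$sample_id[md$role == "qc"])
avg <- average_replicates(filt$table, md)
res <- cln_analysis(avg$table, avg$metadata, "region")
significance_tallies(res)
```
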