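---
title: "Methods: stratified BSE response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified BSE response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bsetrial)
```

`bsetrial` implements the analysis layer of a randomized,
placebo-controlled trial of broccoli sprout extract (BSE) in impaired
fasting glucose, together with synthetic-data generators calibrated to the
trial's reported structure. This vignette is the package's account of the
models, the parameters that matter, the numerical choices, and what the
synthetic calibration does and does not establish.

## The stratification model

Participants are projected onto pathophysiological diabetes clusters
(MARD-, SIRD-, MOD- and SIDD-like) defined on five continuous features:
age (years), BMI (kg/m²), fasting glucose (mmol/l), fasting C-peptide
(nmol/l) and HbA1c (mmol/mol). Glutamic-acid-decarboxylase antibody status,
a binary feature of the source clustering, is treated as uniformly negative
in this population (type 1 diabetes excluded) and is dropped: a constant
feature is degenerate under Euclidean distance.

The projection is a bootstrap procedure:

1. Features are z-scored by the **reference cohort's** mean and SD. The
   source method speaks only of "relative coordinates"; z-scoring is the
   minimal defensible scaling for k-means on mixed-unit features and is the
   package default (`fit_canonical_model`).
2. A canonical k-means model (k = 4 by default) is fitted on the
   standardized reference with greedy k-means++ initialization, Lloyd
   iterations (max 300) and 10 restarts, keeping the lowest total
   within-cluster sum of squares. Determinism comes from the seed.
3. In each of `B` bootstrap rounds, `floor(0.6 n)` reference rows are drawn
   without replacement and re-clustered; round centroids are matched to the
   canonical centroids by exact minimum-cost bipartite assignment
   (enumeration over permutations, k ≤ 8). Without this matching,
   cross-round counts would be meaningless, since k-means labels are
   arbitrary.
4. Every participant is assigned to the nearest round centroid (Euclidean,
   standardized space; exact ties go to the lowest canonical index and are
   counted). Counts over rounds give the modal cluster and the **cluster
   alignment score** max(count)/B ∈ (0, 1].

`B` defaults to 1,000 — the procedure's score granularity is 1/B, and
1,000 rounds resolve scores to 0.001 at modest cost; the number of rounds
used originally is not public. Cluster names are attached by matching
centroids to configurable "hint" centres (`default_cluster_specs()`); the
exact source-cohort centroids are unpublished, so the defaults are
plausible configuration, not claims: MARD-like old/lean/low-C-peptide,
SIRD-like obese/high-C-peptide, MOD-like young/obese, SIDD-like
high-glycaemia/low-C-peptide with a small mixing weight (the trial cohort
occupies essentially three clusters).

A caveat asserted by tests rather than hidden: as cluster separation
shrinks, alignment scores degrade, but not all the way to 1/k — k-means on
overlapping data still splits correlated subsamples along a stable
direction, so scores settle near 0.85 rather than 0.5 in the k = 2
overlap test. The score measures assignment *stability*, not cluster
*reality*.

## Response models and sign conventions

Throughout, **glycaemic improvement** = baseline − week-12 glucose
(positive = reduction), and model outcomes use the **change**
= week-12 − baseline; the two are exact negatives, so a negative treatment
coefficient means BSE lowered glucose.

* `primary_endpoint_model`: OLS of the change on treatment, baseline BMI,
  and the *variation in HOMA-IR*. That phrase is ambiguous; the default
  reads it as the individual 12-week change in HOMA-IR, with baseline
  HOMA-IR selectable (`homa_covariate = "baseline"`).
* `ancova_model`: week-12 glucose on baseline glucose + treatment.
* `interaction_model`: change on treatment × subgroup; the joint
  interaction F-test plus per-subgroup contrasts from the cell-means
  parameterization. Subgroups present in one arm only are dropped with a
  warning.
* `bt2160_cluster_interaction`: among BSE recipients, change on
  log BT2160 × (MARD-like vs pooled SIRD/MOD-like) adjusted for Du Bois
  body surface area. Zeros get a pseudocount of half the smallest nonzero
  abundance before the log.
* `stratified_by_median`: median split of abundance (ties to the lower
  stratum), then MARD vs pooled contrast on improvement within stratum.
* `classify_responders` / `classify_remission`: improvement ≥ 0.3 mmol/l
  (inclusive; or the top-quartile threshold in quantile mode) and week-12
  glucose < 6.1 mmol/l (strict). Both comparisons carry a 1e-8 guard so
  that decimal glucose arithmetic (6.4 − 0.3) honours the inclusive/strict
  rules despite floating-point representation.
* `remission_model`: the reported quantity for the binary remission outcome
  is an R², so the default family is a linear probability model (R² then
  equals the squared correlation of fitted and observed); logistic with
  McFadden pseudo-R² is the sensitivity option.

No multiplicity adjustment is applied anywhere by default, matching the
trial's unadjusted exploratory intervals; `adjust_bh()` exists for
sensitivity reporting. The analysis set is completers only (participants
with post-randomization measures); there is no imputation.

## Microbiome statistics

Bray–Curtis dissimilarity (via `vegan::vegdist`) and classical principal
coordinates (Gower double-centring via `stats::cmdscale`; negative
eigenvalues are reported and their axes dropped — Bray–Curtis is a
semimetric, and the triangle inequality is deliberately *not* asserted).
One-factor PERMANOVA is computed from within/between sums of squared
dissimilarities with label permutations; the two-group gene test permutes
labels around a difference in means, two-sided by default (the sidedness
used originally is unstated; two-sided is the conservative default, with
`alternative = "greater"` available).

Permutation p-values use the add-one convention (1 + b)/(1 + m), so p is
never 0; the gene test also reports `p_plain`, the literal proportion of
permutation statistics at least as extreme (ties count as extreme). Small
problems (two groups) can request `exhaustive = TRUE`, which enumerates all
label assignments and returns the exact proportion — the test suite checks
this against independent brute-force enumeration at n ≤ 8. Gene richness is
a raw detection count (threshold 0 by default; the original normalization
is unstated). The dissimilarity-change test takes an explicit `pre` label
("pre"/"baseline" auto-recognized) after an alphabetical-ordering pitfall
surfaced in development.

## Serum sulforaphane mixture

The concentrations are modelled as a two-component Gaussian mixture with a
**common standard deviation**, fitted by EM with 1-D 2-means
initialization, seeded restarts, a log-likelihood gain threshold of 1e-8
(max 2,000 iterations; EM's crawl near flat optima makes a generous cap
cheaper than spurious non-convergence flags) and an SD floor of 1e-4
against point-mass degeneracy. Components are reported in ascending-mean
order; the log-likelihood trace is returned and is non-decreasing by
construction. High/low classification defaults to posterior responsibility
(> 0.5 for the upper component), which coincides with the midpoint rule in
the equal-weight case; the boundary goes to "low" by the strict rule. The
separation index (μ₂ − μ₁)/σ is ≈ 2 at the packaged calibration — the
regime the trial describes — and values below 2 are flagged as overlapping.

## Power design

The trial's design statement (80% power, effect 0.3 mmol/l, change SD
0.63 mmol/l, α = 0.05, ≈74 participants) is reconciled only by a
**one-sample test on change scores per arm**: the noncentral-t power at
n = 35/arm is 78.1% (80.4% by the normal approximation), and the two-sample
design would need ~70/arm for the same power (it gives ~51% at 35/arm).
The one-sample change design is therefore the default, with the two-sample
design always available. `required_n` inverts the analytic curve by
bisection; `simulate_power` is the Monte Carlo check, and the two agree
within Monte Carlo error across the tested grid.

## What the synthetic generators emulate

The generators are first-class, tested code; their defaults *are* the
study conditions.

* **Trial cohort** (`trial_preset`, `generate_trial_cohort`): baseline
  variables are Gaussian at the published cohort means/SDs (glucose
  6.4 ± 0.2 mmol/l, BMI 32.1 ± 3.8, insulin 18.9 ± 11.1 mIE/l, …), with
  mean-zero cluster offsets on BMI, age and C-peptide expressing the
  cluster phenotypes without disturbing the overall calibration. Cluster
  weights are 51/19/19 (MARD/SIRD/MOD-like), the trial's observed split.
  Improvement ~ Normal(placebo mean + arm·effect(cluster), 0.63); the
  placebo change mean defaults to 0 (not separately reported). Effect
  presets: uniform 0.2 mmol/l (the overall finding), cluster-specific
  0.4 mmol/l in MARD-like only, and a null preset. Week-12 insulin is
  back-computed so that the HOMA-IR change is treatment-independent noise
  (SD 2.2, consistent with the reported null CI for that secondary
  endpoint) — otherwise adjusting for a covariate that contains the glucose
  change would bias the primary-model recovery. Inherently positive
  variables are resampled above zero, with counts recorded.
* **Reference cohort**: Gaussian mixture at the hint centroids; latent
  labels are returned separately and never written into observed tables
  (a schema test enforces this).
* **Microbiome** (`generate_microbiome`): compositional samples × features
  table whose rows sum to exactly 1. BT2160 is lognormal in a latent
  standard-normal score z, calibrated in closed form so that its
  conditional means in the high/low serum-sulforaphane strata (z above/
  below the median for the default 50/50 weight) are 0.032 and 0.022 —
  the scale is read as relative abundance, the units the table carries.
  In copula mode, z is coupled to improvement among MARD-like BSE
  recipients through a Gaussian copula with r = 2·sin(ρₛπ/6), which makes
  the population Spearman correlation of log-abundance with improvement
  exactly the target (−0.47 by default; the correlation applies to the
  improvement variable as configured — the trial reported the association
  on the signed-change scale). In stratified mode, causality is reversed:
  improvement is drawn conditional on the abundance stratum, with a step
  effect of 0.7 mmol/l for MARD-like BSE recipients above the median and 0
  elsewhere, emulating the stratum-specific cluster contrast; the copula
  cannot produce that asymmetric pattern (its conditional shifts are
  symmetric about the median), which is why the two modes exist.
* **Serum sulforaphane** (`generate_sulforaphane`): equal-weight mixture at
  0.2 and 1.3 nmol/ml with common SD 0.55 = (1.3 − 0.2)/2, the direct
  reading of "means differing by about twice the common standard
  deviation". Blank-corrected assay values near the detection limit can be
  slightly negative, so draws are retained as-is by default; censoring at
  zero (`truncate = TRUE`) is available but distorts component-mean
  recovery badly — under censoring, a plain Gaussian EM converges to
  roughly (0.63, 1.59) — so it is not the default.

What passing the calibration tests shows — and does not. At n = 100,000
every preset parameter is recovered within Monte Carlo error, which
validates the *generators* and the *estimators' consistency*. It does not
validate the trial's findings, and the generators deliberately omit
features of real data: measurement error correlated across visits,
non-Gaussian abundance tails, taxon-taxon correlation structure (non-BT2160
features are independent lognormals closed to the simplex), dropout
informative of side effects, and any real taxonomy.

## Numerical choices and degenerate inputs

Exact assignment ties go to the lowest canonical cluster index (counted and
exposed); modal-count ties likewise, flagged per participant. Subsamples
with fewer distinct points than k are redrawn (bounded retries). Zero
variance in a clustering feature is an error naming the feature.
Constant-abundance permutation tests warn and return p = 1. CSV output
serializes doubles at 17 significant digits, so written tables round-trip
exactly; missing week-12 values are empty cells, never sentinels. All
stochastic stages take explicit seeds and are bit-reproducible under them.

## Problem sizes in the shipped tests

The suite keeps references at hundreds to thousands of rows, B at 20–200
rounds, permutation counts at 99–4,000, null-simulation batteries at
500–2,000 replicates, and the calibration recoveries at n = 100,000 —
sizes chosen so the whole suite exercises every claim in minutes on one
core while leaving Monte Carlo noise far below the tolerances it asserts.

## Known limitations

The SIDD-like cluster is nearly unoccupied by construction, so
trial-scale projections can place a handful of participants there with
wide intervals (visible in the README example). Projection
misclassification between MARD- and MOD-like participants dilutes subgroup
contrasts at trial scale — an honest property of the method, not a bug.
PERMANOVA is one-factor only (the repeated-measures adjustment in the
original belongs to its differential-abundance layer, which is out of
scope). HOMA uses the closed HOMA1 forms: the iterative HOMA2 computer
model has no closed form, and the published cohort-mean HOMA-IR is
consistent with HOMA1 applied to the mean inputs; externally computed
HOMA2 columns can be supplied instead. The EM component means at the
packaged overlap (separation 2σ) have an irreducible sampling SD of about
0.037 at n = 2,000; recovery tests use three times that measured SE.
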