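# bsetrial

Stratified treatment-response analysis for a randomized, placebo-controlled
trial of sulforaphane-containing broccoli sprout extract (BSE) in
prediabetes (impaired fasting glucose, 6.1–6.9 mmol/l).

The trial this package models found a modest overall effect of BSE on
fasting glucose, but a markedly larger effect in one pathophysiological
subgroup, modulated by the gut microbiota: participants resembling the mild
age-related diabetes (MARD) cluster, and among them those carrying more of
the *Bacteroides* BT2160 operon (which converts the inactive precursor
glucoraphanin to active sulforaphane), responded most. `bsetrial` packages
the complete analytical machinery of that kind of study — stratification,
response modelling, microbiome statistics, pharmacokinetic mixture
modelling, and power design — as tested, reusable R functions, together
with calibrated synthetic-data generators so every stage runs end to end
without access to the original cohort data.

## What is implemented

**Bootstrap cluster projection.** Participants are assigned to
pathophysiological clusters (MARD/SIRD/MOD/SIDD-like) by k-means projection
against a reference cohort: features (age, BMI, fasting glucose, C-peptide,
HbA1c) are z-scored by reference mean/SD; in each of *B* bootstrap rounds a
60% subsample of the reference is re-clustered (greedy k-means++, Lloyd),
round centroids are matched to the canonical ones by minimum-cost bipartite
assignment, and each participant goes to the nearest centroid in Euclidean
distance. The *cluster alignment score* is the fraction of rounds agreeing
with the modal cluster, in (0, 1].

**Clinical indices.** HOMA1 closed forms
(HOMA-IR = G·I/22.5, HOMA-B = 20·I/(G − 3.5)), the fatty liver index
(logistic 0–100 score from BMI, waist, triglycerides, GGT), the Du Bois
body surface area (0.007184·kg^0.425·cm^0.725), the fasting
C-peptide-to-insulin ratio, IPAQ MET-minutes/week and a 0–9 food score.

**Response models.** Primary linear model of the 12-week glucose change
adjusted for BMI and HOMA-IR variation; ANCOVA; treatment × cluster and
log-BT2160 × cluster interaction models (BSA-adjusted); pronounced-responder
(improvement ≥ 0.3 mmol/l) and remission (week-12 glucose < 6.1 mmol/l)
classification; median-split abundance strata contrasts; remission
regression on BT2160 and GGT.

**Microbiome statistics.** Bray–Curtis dissimilarity, principal
coordinates, one-factor PERMANOVA, two-group gene-abundance permutation
tests (10,000 permutations by default, exact enumeration for small n),
gene richness, and a within-group dissimilarity-change test.

**Serum sulforaphane mixture.** Two-component equal-variance Gaussian
mixture fitted by EM, with a bimodality separation index
((μ₂ − μ₁)/σ ≈ 2 at the packaged calibration) and high/low classification
feeding the abundance-strata analysis.

**Power design.** Noncentral-t and Monte Carlo power for the one-sample
change-score design (the configuration that reconciles the trial's stated
80% power, SD 0.63 mmol/l, effect 0.3 mmol/l and ≈74 participants) and the
two-sample alternative; minimal-n search.

## Worked example

```r
library(bsetrial)

# a synthetic trial: 500/arm, cluster-specific effect (0.4 mmol/l in MARD-like)
spec   <- trial_preset(effect = "cluster_specific",
                       n_per_arm = c(BSE = 500, placebo = 500))
cohort <- generate_trial_cohort(spec, seed = 42)

# project participants onto reference clusters (B = 200 bootstrap rounds)
ref   <- generate_reference_cohort(4000, seed = 42)
hints <- t(sapply(default_cluster_specs(), function(s) s$means))
proj  <- run_bootstrap_assignment(ref$features,
                                  clustering_features(cohort$records),
                                  k = 4, B = 200, seed = 42,
                                  label_hints = hints)
table(proj$assignments$modal_label)
#> MARD  MOD SIDD SIRD
#>  574  180    4  242
mean(proj$assignments$alignment_score)
#> 0.998

primary_endpoint_model(cohort$records)
#>     estimate     ci_low    ci_high      p_value n_used
#> 1 -0.2957019 -0.3742993 -0.2171045 3.267715e-13   1000

im <- interaction_model(cohort$records, proj$assignments$modal_label)
im$contrasts
#>   group estimate ci_low ci_high p_value   n
#> 1  MARD   -0.405 -0.507  -0.302   0.000 574
#> 2   MOD   -0.291 -0.475  -0.107   0.002 180
#> 3  SIDD   -0.716 -2.135   0.704   0.323   4
#> 4  SIRD   -0.021 -0.179   0.138   0.799 242
im$interaction_p
#> 0.00103
```

The primary estimate (−0.30 mmol/l here) is the BSE-minus-placebo
difference in glucose change — negative means BSE lowered glucose — and the
per-cluster contrasts recover the generator's heterogeneity: the MARD-like
contrast is near the simulated −0.4 mmol/l while SIRD-like is null, and the
interaction test flags the difference. (The MOD-like contrast is partly
contaminated by projection misclassification; the trial-scale noise you see
is real.)

The bimodal serum concentrations and the design calculation:

```r
fit <- fit_two_component(generate_sulforaphane(2000, seed = 42)$values, seed = 1)
fit
#> Two-component equal-variance Gaussian mixture
#>   means: 0.1640 / 1.2630  (common sd 0.5519)
#>   weights: 0.457 / 0.543
#>   log-likelihood -2315.385 after 82 iterations (converged)
bimodality_separation(fit)   # ~2 common SDs apart
#> 1.99
analytic_power(0.3, 0.63, 35)   # one-sample change design
#> 0.781
required_n(0.3, 0.63, power = 0.8)
#> 37
```

A command-line front end mirrors the pipeline
(`simulate`, `indices`, `cluster`, `respond`, `microbiome`, `mixture`,
`power`, `report`); see `inst/scripts/bsetrial` and `?run_cli`.

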