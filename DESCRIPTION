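Package: bsetrial
Title: Stratified Treatment-Response Analysis for a Broccoli Sprout Extract
    Trial in Prediabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable pipeline for stratified analysis of a randomized
    broccoli sprout extract (BSE) trial in impaired fasting glucose:
    bootstrap projection of participants onto pathophysiological k-means
    clusters (MARD/SIRD/MOD-like) with a cluster alignment score, derived
    clinical indices (HOMA, fatty liver index, Du Bois body surface area,
    IPAQ MET-minutes), cluster-aware and microbiome-aware (BT2160 operon)
    treatment-response models, community-level microbiome statistics
    (Bray-Curtis dissimilarity, principal coordinates, PERMANOVA, gene
    permutation tests), two-component Gaussian mixture modelling of
    bimodal serum sulforaphane, and analytic plus Monte Carlo trial power
    design. Includes calibrated synthetic-data generators so the full
    pipeline is testable end to end without access to cohort microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
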