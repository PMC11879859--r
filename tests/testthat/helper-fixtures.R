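# Programmatic fixtures shared across the suite.

# minimal valid trial table with n completers per arm and prescribed
# improvements (baseline - week12 glucose); other fields filled plausibly
make_trial <- function(improvement_bse, improvement_placebo,
                       baseline_glucose = 6.4) {
  n_b <- length(improvement_bse)
  n_p <- length(improvement_placebo)
  n <- n_b + n_p
  imp <- c(improvement_bse, improvement_placebo)
  g0 <- rep(baseline_glucose, n)
  d <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    arm = c(rep("BSE", n_b), rep("placebo", n_p)),
    completed = TRUE, age = 63,
    baseline_glucose = g0, baseline_insulin = 18.9,
    baseline_c_peptide = 1.22, baseline_hba1c = 38.2,
    baseline_bmi = 32.1, baseline_waist = 110,
    baseline_triglycerides = 1.5, baseline_ggt = 0.7,
    baseline_weight = 95, baseline_height = 172,
    week12_glucose = g0 - imp, week12_insulin = 18.9,
    week12_c_peptide = 1.22, week12_hba1c = 38.2,
    week12_bmi = 32.1, week12_waist = 110,
    week12_triglycerides = 1.5, week12_ggt = 0.7,
    week12_weight = 95,
    serum_sulforaphane = NA_real_,
    stringsAsFactors = FALSE)
  d
}

# 2-D point clouds for Euclidean distance toys
euclid_dist <- function(points) as.matrix(stats::dist(points))

# fraction of latent labels recovered by a labelled assignment
recovery_rate <- function(assigned, latent) mean(assigned == latent)

# cluster-naming hints from the default specs
default_hints <- function() {
  specs <- default_cluster_specs()
  t(sapply(specs, function(s) s$means))
}
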