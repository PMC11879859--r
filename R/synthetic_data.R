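# Synthetic-data generators. These emulate the statistical structure the
# trial reports — baseline calibration, cluster structure, heterogeneous
# treatment effects, BT2160 abundance strata with a rank-calibrated link to
# glycaemic response, and bimodal serum sulforaphane — so every downstream
# stage is testable without cohort microdata. All generators are
# deterministic under their seed. Latent labels (cluster, mixture component,
# sulforaphane stratum) are returned separately and are never written into
# the observed trial table.

resample_positive <- function(n, mean, sd, max_tries = 50, floor = 0) {
  x <- stats::rnorm(n, mean, sd)
  tries <- 0
  count <- 0L
  while (any(x <= floor)) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("could not generate positive values for mean ", mean, ", sd ", sd)
    bad <- x <= floor
    count <- count + sum(bad)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  attr(x, "resample_count") <- count
  x
}

#' Generate a synthetic reference cohort for cluster projection
#'
#' Draws `n` individuals from the Gaussian mixture defined by the cluster
#' specifications (see [default_cluster_specs()]), in the natural units of
#' the clustering features. Latent true cluster labels are returned alongside
#' the features for recovery testing, never inside the feature table.
#'
#' @param n Number of individuals (>= number of clusters).
#' @param specs Named list of cluster specs (`label`, `means`, `sds`,
#'   `weight`).
#' @param seed Integer seed.
#' @return List with `features` (data.frame, one column per clustering
#'   feature) and `latent` (character vector of true cluster labels).
#' @export
generate_reference_cohort <- function(n, specs = default_cluster_specs(),
                                      seed = 1) {
  k <- length(specs)
  if (n < k) stop("n must be at least the number of clusters (", k, ")")
  w <- vapply(specs, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) stop("cluster weights must sum to 1")
  feat <- names(specs[[1]]$means)
  set.seed(seed)
  latent <- sample(names(specs), n, replace = TRUE, prob = w)
  x <- matrix(NA_real_, n, length(feat), dimnames = list(NULL, feat))
  for (cl in names(specs)) {
    idx <- which(latent == cl)
    if (!length(idx)) next
    for (f in feat)
      x[idx, f] <- stats::rnorm(length(idx), specs[[cl]]$means[[f]],
                                specs[[cl]]$sds[[f]])
  }
  list(features = as.data.frame(x), latent = latent)
}

#' Generate a synthetic randomized trial cohort
#'
#' Draws baseline clinical variables from the preset calibration (overall
#' mean/SD per variable, with mean-zero cluster offsets for BMI, age and
#' C-peptide), assigns each participant a latent pathophysiological cluster,
#' and sets the week-12 glucose as
#' `baseline - improvement` with
#' `improvement ~ Normal(placebo_change_mean + arm * effect[cluster], change_sd)`,
#' so that positive improvement means a glucose reduction. Week-12 insulin is
#' back-computed so that the individual change in HOMA-IR is
#' treatment-independent noise, reflecting the trial's null secondary
#' endpoint for insulin resistance. Negative draws of inherently positive
#' variables are resampled (counts recorded in the `resample_count`
#' attribute).
#'
#' @param spec A specification from [trial_preset()].
#' @param seed Integer seed.
#' @return List with `records` (a validated [trial_schema()] data.frame) and
#'   `latent` (data.frame with `participant_id` and true `cluster`).
#' @export
generate_trial_cohort <- function(spec = trial_preset(), seed = 1) {
  set.seed(seed)
  n_bse <- spec$n_per_arm[["BSE"]]
  n_pla <- spec$n_per_arm[["placebo"]]
  n <- n_bse + n_pla
  arm <- c(rep("BSE", n_bse), rep("placebo", n_pla))
  clusters <- names(spec$cluster_mix)
  latent <- sample(clusters, n, replace = TRUE, prob = spec$cluster_mix)

  resamples <- 0L
  draw_var <- function(var, positive = TRUE) {
    cal <- spec$baseline[[var]]
    off <- spec$cluster_offsets[[var]]
    mu <- rep(cal$mean, n)
    sd_i <- cal$sd
    if (!is.null(off)) {
      offv <- unlist(off)[latent]
      between <- sum(spec$cluster_mix * unlist(off)[clusters]^2)
      within <- sqrt(max(cal$sd^2 - between, (0.25 * cal$sd)^2))
      mu <- mu + offv
      sd_i <- within
    }
    if (positive) {
      x <- resample_positive(n, mu, sd_i)
      resamples <<- resamples + attr(x, "resample_count")
      as.numeric(x)
    } else stats::rnorm(n, mu, sd_i)
  }

  glucose0 <- draw_var("glucose")
  insulin0 <- draw_var("insulin")
  cpep0 <- draw_var("c_peptide")
  hba1c0 <- draw_var("hba1c")
  bmi0 <- draw_var("bmi")
  waist0 <- draw_var("waist")
  tg0 <- draw_var("triglycerides")
  ggt0 <- draw_var("ggt")
  height <- draw_var("height")
  age <- draw_var("age")
  weight0 <- bmi0 * (height / 100)^2

  effect <- spec$effect_by_cluster[latent]
  improvement <- stats::rnorm(
    n, spec$placebo_change_mean + (arm == "BSE") * effect, spec$change_sd)
  glucose12 <- glucose0 - improvement
  tries <- 0
  while (any(glucose12 <= 0)) {
    tries <- tries + 1
    if (tries > 50) stop("persistent non-positive week-12 glucose")
    bad <- glucose12 <= 0
    resamples <- resamples + sum(bad)
    improvement[bad] <- stats::rnorm(
      sum(bad), spec$placebo_change_mean + (arm[bad] == "BSE") * effect[bad],
      spec$change_sd)
    glucose12[bad] <- glucose0[bad] - improvement[bad]
  }

  # week-12 insulin via a treatment-independent HOMA-IR drift
  homa0 <- glucose0 * insulin0 / 22.5
  homa12 <- pmax(homa0 + stats::rnorm(n, 0, spec$homa_change_sd), 0.2)
  insulin12 <- 22.5 * homa12 / glucose12

  drift <- function(x, var, floor = 0.01) {
    sd_d <- spec$week12_drift_sd[[var]]
    pmax(x + stats::rnorm(n, 0, sd_d), floor)
  }
  cpep12 <- drift(cpep0, "c_peptide")
  hba1c12 <- drift(hba1c0, "hba1c", floor = 10)
  bmi12 <- drift(bmi0, "bmi", floor = 10)
  waist12 <- drift(waist0, "waist", floor = 40)
  tg12 <- drift(tg0, "triglycerides")
  ggt12 <- drift(ggt0, "ggt")
  weight12 <- bmi12 * (height / 100)^2

  completed <- rep(TRUE, n)
  if (spec$dropout_rate > 0)
    completed <- stats::runif(n) >= spec$dropout_rate

  records <- data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    arm = arm, completed = completed, age = age,
    baseline_glucose = glucose0, baseline_insulin = insulin0,
    baseline_c_peptide = cpep0, baseline_hba1c = hba1c0,
    baseline_bmi = bmi0, baseline_waist = waist0,
    baseline_triglycerides = tg0, baseline_ggt = ggt0,
    baseline_weight = weight0, baseline_height = height,
    week12_glucose = glucose12, week12_insulin = insulin12,
    week12_c_peptide = cpep12, week12_hba1c = hba1c12,
    week12_bmi = bmi12, week12_waist = waist12,
    week12_triglycerides = tg12, week12_ggt = ggt12,
    week12_weight = weight12,
    serum_sulforaphane = NA_real_,
    stringsAsFactors = FALSE)
  wk <- grep("^week12_", names(records), value = TRUE)
  records[!completed, wk] <- NA_real_
  validate_trial_dataset(records)
  attr(records, "resample_count") <- resamples
  list(records = records,
       latent = data.frame(participant_id = records$participant_id,
                           cluster = latent, stringsAsFactors = FALSE))
}

#' Generate serum sulforaphane concentrations
#'
#' Draws from a two-component equal-variance Gaussian mixture (component
#' means `mean_low`/`mean_high`, weight `weight_high` on the upper
#' component). Blank-corrected assay concentrations may be slightly negative,
#' so draws are kept as-is by default; with `spec$truncate = TRUE` negative
#' draws are resampled within their component.
#'
#' @param n Number of draws.
#' @param spec Specification from [sulforaphane_preset()].
#' @param seed Integer seed.
#' @return List with `values` (nmol/ml) and `component` (latent labels
#'   `"low"`/`"high"`).
#' @export
generate_sulforaphane <- function(n, spec = sulforaphane_preset(), seed = 1) {
  stopifnot(spec$common_sd > 0)
  set.seed(seed)
  comp <- ifelse(stats::runif(n) < spec$weight_high, "high", "low")
  mu <- ifelse(comp == "high", spec$mean_high, spec$mean_low)
  x <- stats::rnorm(n, mu, spec$common_sd)
  if (isTRUE(spec$truncate)) {
    while (any(x < 0)) {
      bad <- x < 0
      x[bad] <- stats::rnorm(sum(bad), mu[bad], spec$common_sd)
    }
  }
  list(values = x, component = comp)
}

# Lognormal calibration of the BT2160 feature: abundance = exp(m + s*z) with
# z standard normal and stratum = (z > c), c the (1 - high_weight) quantile.
# s and m solve E[abund | high] = mean_high, E[abund | low] = mean_low.
bt2160_lognormal_params <- function(mean_high, mean_low, high_weight) {
  cutoff <- stats::qnorm(1 - high_weight)
  ratio <- function(s) {
    (exp(s^2 / 2) * stats::pnorm(s - cutoff) / (1 - stats::pnorm(cutoff))) /
      (exp(s^2 / 2) * (1 - stats::pnorm(s - cutoff)) / stats::pnorm(cutoff))
  }
  s <- stats::uniroot(function(s) ratio(s) - mean_high / mean_low,
                      c(1e-6, 10))$root
  m <- log(mean_high * (1 - stats::pnorm(cutoff)) /
             (exp(s^2 / 2) * stats::pnorm(s - cutoff)))
  list(m = m, s = s, cutoff = cutoff)
}

#' Generate a linked microbiome abundance table
#'
#' Builds a compositional samples-by-features abundance table (per-sample
#' feature sums exactly 1) for a trial cohort, with one designated
#' `BT2160` feature.
#'
#' The BT2160 feature is lognormal in a latent standard-normal score `z`,
#' calibrated so that its conditional means in the high and low
#' serum-sulforaphane strata (`z` above/below the `1 - high_weight`
#' quantile) equal the preset stratum means. Two linkage modes:
#'
#' * `"copula"` (default): among MARD-like BSE recipients, `z` is coupled to
#'   the participant's glycaemic improvement through a Gaussian copula with
#'   correlation `2 sin(rho_s * pi / 6)`, so the population Spearman
#'   correlation between log BT2160 abundance and improvement equals
#'   `spearman_target`; elsewhere `z` is independent noise.
#' * `"stratified"`: `z` is independent noise everywhere and the glycaemic
#'   improvement is instead drawn conditional on the abundance stratum — a
#'   step effect of `stratified_effect` mmol/l for MARD-like BSE recipients
#'   above the median abundance, zero elsewhere — emulating the
#'   stratum-specific cluster contrast.
#'
#' Serum sulforaphane values are drawn from the mixture component matching
#' each participant's stratum.
#'
#' @param cohort A cohort from [generate_trial_cohort()] (list with `records`
#'   and `latent`).
#' @param spec Specification from [bt2160_preset()].
#' @param n_features Total number of features (including BT2160).
#' @param mode `"copula"` or `"stratified"`, see Details.
#' @param sulf_spec Mixture spec for the linked serum concentrations.
#' @param seed Integer seed.
#' @return List with `abundance` (matrix, samples x features, rows named by
#'   participant id, one column `BT2160`) and `meta` (data.frame:
#'   `participant_id`, `arm`, `cluster`, `improvement`, `bt2160`,
#'   `sulf_stratum`, `serum_sulforaphane`).
#' @export
generate_microbiome <- function(cohort, spec = bt2160_preset(),
                                n_features = spec$n_features,
                                mode = c("copula", "stratified"),
                                sulf_spec = sulforaphane_preset(),
                                seed = 1) {
  mode <- match.arg(mode)
  if (abs(spec$spearman_target) >= 1)
    stop("spearman_target must have absolute value < 1")
  rec <- cohort$records
  lat <- cohort$latent
  stopifnot(identical(rec$participant_id, lat$participant_id))
  n <- nrow(rec)
  improvement <- rec$baseline_glucose - rec$week12_glucose
  cluster <- lat$cluster
  arm <- rec$arm

  set.seed(seed)
  eps <- stats::rnorm(n)
  if (mode == "copula") {
    r <- 2 * sin(spec$spearman_target * pi / 6)
    z <- eps
    link <- which(cluster == "MARD" & arm == "BSE" & !is.na(improvement))
    if (length(link) > 1) {
      zi <- as.numeric(scale(improvement[link]))
      z[link] <- r * zi + sqrt(1 - r^2) * eps[link]
    }
  } else {
    z <- eps
  }

  par <- bt2160_lognormal_params(spec$stratum_mean_high,
                                 spec$stratum_mean_low, spec$high_weight)
  bt <- exp(par$m + par$s * z)
  stratum <- ifelse(z > par$cutoff, "high", "low")

  if (mode == "stratified") {
    # improvement drawn conditional on the (population-median) stratum
    above <- z > stats::qnorm(0.5)
    mu <- ifelse(cluster == "MARD" & arm == "BSE" & above,
                 spec$stratified_effect, 0)
    improvement <- stats::rnorm(n, mu, spec$change_sd)
  }

  serum <- stats::rnorm(n, ifelse(stratum == "high", sulf_spec$mean_high,
                                  sulf_spec$mean_low), sulf_spec$common_sd)

  other <- matrix(stats::rlnorm(n * (n_features - 1), 0,
                                spec$other_features_log_sd),
                  nrow = n)
  other <- other / rowSums(other) * (1 - bt)
  abundance <- cbind(BT2160 = bt, other)
  colnames(abundance) <- c("BT2160",
                           sprintf("feature_%03d", seq_len(n_features - 1)))
  rownames(abundance) <- rec$participant_id

  list(abundance = abundance,
       meta = data.frame(participant_id = rec$participant_id, arm = arm,
                         cluster = cluster, improvement = improvement,
                         bt2160 = bt, sulf_stratum = stratum,
                         serum_sulforaphane = serum,
                         stringsAsFactors = FALSE))
}
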