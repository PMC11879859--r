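# Endpoint and subgroup analyses. Sign discipline, used throughout:
# glycaemic improvement = baseline - week12 (positive = glucose reduction);
# model outcomes use the change = week12 - baseline, so a negative treatment
# coefficient means BSE lowered glucose. The two are exact negatives.

completers <- function(dataset) {
  d <- as.data.frame(dataset)
  d[d$completed & !is.na(d$week12_glucose), , drop = FALSE]
}

#' Glycaemic improvement (baseline minus week-12 glucose)
#'
#' @param dataset A trial dataset.
#' @return Numeric vector, mmol/l; positive values are reductions. NA for
#'   non-completers.
#' @export
glycaemic_improvement <- function(dataset) {
  dataset$baseline_glucose - dataset$week12_glucose
}

effect_row <- function(fit, term, n_used, descriptor) {
  cf <- summary(fit)$coefficients
  ci <- tryCatch(stats::confint(fit, term, level = 0.95),
                 error = function(e) c(NA_real_, NA_real_))
  data.frame(estimate = cf[term, "Estimate"],
             ci_low = ci[1], ci_high = ci[2],
             p_value = cf[term, "Pr(>|t|)"],
             n_used = n_used,
             model_descriptor = descriptor,
             stringsAsFactors = FALSE, row.names = NULL)
}

arm_factor <- function(arm) factor(arm, levels = c("placebo", "BSE"))

#' Primary endpoint model: change in fasting glucose
#'
#' Ordinary least squares of the 12-week change in fasting glucose
#' (week12 - baseline) on the treatment indicator, adjusted for baseline BMI
#' and for the variation in HOMA-IR — by default the individual change in
#' HOMA-IR over the 12 weeks (`homa_covariate = "change"`); the baseline
#' HOMA-IR alternative is selectable. Only completers enter (full analysis
#' set). The returned treatment coefficient is BSE minus placebo, so a
#' negative estimate means BSE lowered glucose.
#'
#' @param dataset A trial dataset.
#' @param homa_covariate `"change"` (default) or `"baseline"`.
#' @return One-row data.frame: `estimate`, `ci_low`, `ci_high`, `p_value`,
#'   `n_used`, `model_descriptor`.
#' @export
primary_endpoint_model <- function(dataset,
                                   homa_covariate = c("change", "baseline")) {
  homa_covariate <- match.arg(homa_covariate)
  d <- completers(dataset)
  if (length(unique(d$arm)) < 2 || min(table(d$arm)) < 2)
    stop("need at least 2 completers per arm")
  d$dglucose <- d$week12_glucose - d$baseline_glucose
  d$homa0 <- d$baseline_glucose * d$baseline_insulin / 22.5
  if (homa_covariate == "change") {
    d$homa_cov <- d$week12_glucose * d$week12_insulin / 22.5 - d$homa0
    lab <- "dHOMA-IR"
  } else {
    d$homa_cov <- d$homa0
    lab <- "baseline HOMA-IR"
  }
  d$treat <- arm_factor(d$arm)
  fit <- stats::lm(dglucose ~ treat + baseline_bmi + homa_cov, data = d)
  effect_row(fit, "treatBSE", nrow(d),
             paste0("dglucose ~ arm + BMI + ", lab))
}

#' ANCOVA model for week-12 glucose
#'
#' OLS of week-12 glucose on baseline glucose and treatment; the treatment
#' coefficient (BSE minus placebo) is returned.
#'
#' @param dataset A trial dataset.
#' @return One-row effect data.frame as in [primary_endpoint_model()].
#' @export
ancova_model <- function(dataset) {
  d <- completers(dataset)
  if (length(unique(d$arm)) < 2 || min(table(d$arm)) < 2)
    stop("need at least 2 completers per arm")
  d$treat <- arm_factor(d$arm)
  fit <- stats::lm(week12_glucose ~ baseline_glucose + treat, data = d)
  effect_row(fit, "treatBSE", nrow(d), "week12 ~ baseline + arm")
}

#' Treatment-by-subgroup interaction model
#'
#' OLS of the glucose change on treatment, subgroup and their interaction.
#' Returns the joint interaction test (F-test comparing the additive and
#' interaction models) and per-subgroup treatment contrasts (BSE minus
#' placebo within each subgroup, from the cell-means parameterization).
#' Subgroups present in only one arm are dropped with a warning.
#'
#' @param dataset A trial dataset.
#' @param grouping Subgroup label per dataset row (e.g. modal cluster
#'   labels).
#' @return List with `interaction_p` (joint F-test p-value) and `contrasts`
#'   (data.frame: `group`, `estimate`, `ci_low`, `ci_high`, `p_value`, `n`).
#' @export
interaction_model <- function(dataset, grouping) {
  d <- as.data.frame(dataset)
  stopifnot(length(grouping) == nrow(d))
  d$group <- as.character(grouping)
  d <- completers(d)
  keep <- names(which(apply(table(d$group, d$arm) > 0, 1, all)))
  dropped <- setdiff(unique(d$group), keep)
  if (length(dropped)) {
    warning("subgroup(s) present in only one arm dropped: ",
            paste(dropped, collapse = ", "))
    d <- d[d$group %in% keep, , drop = FALSE]
  }
  if (length(keep) < 2) stop("need >= 2 subgroups present in both arms")
  d$dglucose <- d$week12_glucose - d$baseline_glucose
  d$treat <- arm_factor(d$arm)
  d$group <- factor(d$group)
  fit_add <- stats::lm(dglucose ~ treat + group, data = d)
  fit_full <- stats::lm(dglucose ~ treat * group, data = d)
  p_int <- stats::anova(fit_add, fit_full)[2, "Pr(>F)"]
  # cell-means side: per-group treatment contrasts with their own SEs
  fit_cm <- stats::lm(dglucose ~ 0 + group + group:treat, data = d)
  cf <- summary(fit_cm)$coefficients
  ci <- stats::confint(fit_cm)
  terms <- paste0("group", levels(d$group), ":treatBSE")
  contrasts <- data.frame(
    group = levels(d$group),
    estimate = cf[terms, "Estimate"],
    ci_low = ci[terms, 1], ci_high = ci[terms, 2],
    p_value = cf[terms, "Pr(>|t|)"],
    n = as.integer(table(d$group)[levels(d$group)]),
    stringsAsFactors = FALSE, row.names = NULL)
  list(interaction_p = p_int, contrasts = contrasts)
}

#' Classify pronounced responders in the BSE arm
#'
#' Fixed mode labels a BSE completer a pronounced responder when the
#' glycaemic improvement is at least `threshold` (inclusive; default
#' 0.3 mmol/l). Quantile mode instead uses the 75th percentile of the
#' observed improvements as the (inclusive) threshold, matching a
#' "top quartile of improvement" definition; with heavy ties this labels
#' all tied-at-threshold participants responders.
#'
#' @param dataset A trial dataset.
#' @param mode `"fixed"` (default) or `"quantile"`.
#' @param threshold Improvement threshold for fixed mode, mmol/l.
#' @return Data.frame for BSE completers: `participant_id`, `improvement`,
#'   `pronounced_responder`, plus the applied `threshold` as an attribute.
#' @export
classify_responders <- function(dataset, mode = c("fixed", "quantile"),
                                threshold = 0.3) {
  mode <- match.arg(mode)
  d <- completers(dataset)
  d <- d[d$arm == "BSE", , drop = FALSE]
  if (!nrow(d)) stop("no BSE-arm completers")
  imp <- glycaemic_improvement(d)
  thr <- if (mode == "fixed") threshold
         else as.numeric(stats::quantile(imp, 0.75))
  # absolute guard keeps the inclusive rule robust to floating-point
  # representation of decimal glucose readings (e.g. 6.4 - 6.1)
  out <- data.frame(participant_id = d$participant_id, improvement = imp,
                    pronounced_responder = imp >= thr - 1e-8,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  out
}

#' Classify remission of impaired fasting glucose
#'
#' Remission is a week-12 fasting glucose strictly below 6.1 mmol/l.
#'
#' @param dataset A trial dataset.
#' @param arm Which arm to classify (default `"BSE"`, the paper's remission
#'   analysis; use `NULL` for all completers).
#' @return Data.frame: `participant_id`, `week12_glucose`, `remission`.
#' @export
classify_remission <- function(dataset, arm = "BSE") {
  d <- completers(dataset)
  if (!is.null(arm)) d <- d[d$arm == arm, , drop = FALSE]
  # strict rule with a floating-point guard: values within 1e-8 of the
  # 6.1 mmol/l boundary count as at the boundary, hence not remission
  data.frame(participant_id = d$participant_id,
             week12_glucose = d$week12_glucose,
             remission = d$week12_glucose < 6.1 - 1e-8,
             stringsAsFactors = FALSE)
}

log_with_pseudocount <- function(x) {
  if (any(x < 0)) stop("negative abundance")
  if (any(x == 0)) {
    pc <- min(x[x > 0]) / 2
    x <- x + pc
  }
  log(x)
}

#' BT2160-by-cluster interaction on the glycaemic response to BSE
#'
#' Among BSE recipients, OLS of the glucose change (week12 - baseline) on
#' log BT2160 abundance, the binary subgroup (MARD-like versus SIRD/MOD-like
#' pooled), their interaction, and body surface area as an adjustment
#' covariate. Zero abundances receive a pseudocount of half the smallest
#' nonzero value before the log. The interaction coefficient is returned.
#'
#' @param dglucose Glucose change (week12 - baseline), mmol/l, BSE
#'   completers.
#' @param bt2160 BT2160 relative abundance (>= 0).
#' @param cluster Cluster label per participant (`"MARD"` versus others).
#' @param bsa Body surface area, m^2 (Du Bois).
#' @return One-row effect data.frame for the interaction term.
#' @export
bt2160_cluster_interaction <- function(dglucose, bt2160, cluster, bsa) {
  stopifnot(length(dglucose) == length(bt2160),
            length(cluster) == length(dglucose),
            length(bsa) == length(dglucose))
  d <- data.frame(dglucose = dglucose,
                  log_bt = log_with_pseudocount(bt2160),
                  mard = factor(ifelse(cluster == "MARD", "MARD", "other"),
                                levels = c("other", "MARD")),
                  bsa = bsa)
  fit <- stats::lm(dglucose ~ log_bt * mard + bsa, data = d)
  effect_row(fit, "log_bt:mardMARD", nrow(d),
             "dglucose ~ logBT2160 * MARD + BSA")
}

#' Cluster contrasts within BT2160 median strata
#'
#' Splits BSE recipients at the sample median of BT2160 abundance (values
#' equal to the median go to the lower stratum) and, within each stratum,
#' contrasts the glycaemic improvement of MARD-like versus pooled
#' SIRD/MOD-like participants by OLS. A stratum missing either subgroup is
#' skipped with a warning.
#'
#' @param improvement Glycaemic improvement (baseline - week12), mmol/l.
#' @param bt2160 BT2160 abundance per participant.
#' @param cluster Cluster label per participant.
#' @return Data.frame, one row per stratum: `stratum` ("below"/"above"),
#'   `estimate` (MARD minus other, improvement units), `ci_low`, `ci_high`,
#'   `p_value`, `n`.
#' @export
stratified_by_median <- function(improvement, bt2160, cluster) {
  stopifnot(length(improvement) == length(bt2160),
            length(cluster) == length(improvement))
  med <- stats::median(bt2160)
  stratum <- ifelse(bt2160 > med, "above", "below")
  mard <- factor(ifelse(cluster == "MARD", "MARD", "other"),
                 levels = c("other", "MARD"))
  out <- NULL
  for (s in c("below", "above")) {
    idx <- stratum == s
    if (length(unique(mard[idx])) < 2 || min(table(mard[idx])) < 2) {
      warning("stratum '", s, "' lacks both subgroups; skipped")
      next
    }
    fit <- stats::lm(improvement[idx] ~ mard[idx])
    row <- effect_row(fit, "mard[idx]MARD", sum(idx),
                      "improvement ~ MARD | stratum")
    row <- cbind(stratum = s, row, stringsAsFactors = FALSE)
    out <- rbind(out, row)
  }
  names(out)[names(out) == "n_used"] <- "n"
  out$model_descriptor <- NULL
  out
}

#' Remission regression on BT2160 abundance and GGT
#'
#' Regression of remission status on log BT2160 abundance and plasma GGT.
#' The default is a linear probability model, reporting the model R-squared
#' (the quantity reported for the corresponding binary-outcome model) and
#' per-covariate p-values; a logistic alternative reports McFadden's
#' pseudo-R-squared.
#'
#' @param remission Logical remission status.
#' @param bt2160 BT2160 abundance (logged internally, with pseudocount).
#' @param ggt Plasma GGT, ukat/l.
#' @param family `"linear"` (default) or `"logistic"`.
#' @return List with `r_squared`, `p_values` (named: `bt2160`, `ggt`),
#'   `coefficients`, `family`.
#' @export
remission_model <- function(remission, bt2160, ggt,
                            family = c("linear", "logistic")) {
  family <- match.arg(family)
  stopifnot(is.logical(remission))
  if (length(unique(remission)) < 2)
    stop("remission outcome is constant; model undefined")
  d <- data.frame(y = as.numeric(remission),
                  log_bt = log_with_pseudocount(bt2160), ggt = ggt)
  if (family == "linear") {
    fit <- stats::lm(y ~ log_bt + ggt, data = d)
    r2 <- summary(fit)$r.squared
    cf <- summary(fit)$coefficients
    p <- cf[c("log_bt", "ggt"), "Pr(>|t|)"]
  } else {
    fit <- stats::glm(y ~ log_bt + ggt, data = d, family = stats::binomial())
    null_dev <- fit$null.deviance
    r2 <- 1 - fit$deviance / null_dev
    cf <- summary(fit)$coefficients
    p <- cf[c("log_bt", "ggt"), "Pr(>|z|)"]
  }
  list(r_squared = r2,
       p_values = c(bt2160 = unname(p[1]), ggt = unname(p[2])),
       coefficients = stats::coef(fit),
       family = family)
}

#' Benjamini-Hochberg adjustment utility
#'
#' Convenience wrapper around [stats::p.adjust()] with the FDR method.
#' Multiplicity adjustment is off by default throughout the package
#' (confidence intervals and p-values are unadjusted, as in the trial
#' analysis); this utility is for optional sensitivity reporting.
#'
#' @param p Numeric p-values.
#' @return Adjusted p-values.
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")
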