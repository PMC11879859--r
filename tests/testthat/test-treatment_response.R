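test_that("primary endpoint model recovers a noise-free treatment effect", {
  d <- make_trial(rep(0.5, 6) + (1:6) * 1e-12, rep(0, 6) + (1:6) * 1e-12)
  # vary BMI/HOMA slightly so the design is nonsingular
  d$baseline_bmi <- d$baseline_bmi + seq(-0.5, 0.6, length.out = 12)
  d$week12_insulin <- d$week12_insulin + seq(0, 1.1, length.out = 12)
  est <- suppressWarnings(primary_endpoint_model(d))  # perfect-fit notice
  expect_equal(est$estimate, -0.5, tolerance = 1e-6)
  expect_equal(est$n_used, 12)
  one_arm <- make_trial(rep(0.2, 5), numeric(0))
  expect_error(primary_endpoint_model(one_arm), "per arm")
})

test_that("ANCOVA equals the change-score model when baseline slope is 1", {
  set.seed(31)
  imp_b <- rnorm(40, 0.5, 0.3)
  imp_p <- rnorm(40, 0, 0.3)
  d <- make_trial(imp_b, imp_p)
  d$baseline_glucose <- d$baseline_glucose + rnorm(80, 0, 0.2)
  d$week12_glucose <- d$baseline_glucose - c(imp_b, imp_p)
  anc <- ancova_model(d)
  # offsetting week12 by baseline (slope forced to 1) = change-score model
  treat <- factor(d$arm, levels = c("placebo", "BSE"))
  ch_fit <- lm(I(d$week12_glucose - d$baseline_glucose) ~ treat)
  anc_fit <- lm(d$week12_glucose ~ treat + offset(d$baseline_glucose))
  expect_equal(unname(coef(ch_fit)["treatBSE"]),
               unname(coef(anc_fit)["treatBSE"]), tolerance = 1e-12)
  # with estimated slope, estimate is close but from the ANCOVA family
  expect_lt(abs(anc$estimate - (-0.5)), 0.2)
})

test_that("interaction model matches cell-mean algebra on a two-group toy", {
  set.seed(35)
  eps <- rnorm(40, 0, 1e-4)  # break perfect collinearity, keep cell means
  imp_b <- c(rep(0.6, 10), rep(0.1, 10)) + eps[1:20]   # groups A, B / BSE
  imp_p <- c(rep(0.1, 10), rep(0.1, 10)) + eps[21:40]  # groups A, B / placebo
  d <- make_trial(imp_b, imp_p)
  grp <- rep(c("A", "B", "A", "B"), each = 10)
  res <- interaction_model(d, grp)
  # cell means: effect in A = -(0.6-0.1) = -0.5, in B = 0
  cm <- function(g, a) mean(glycaemic_improvement(d)[grp == g & d$arm == a])
  expect_equal(res$contrasts$estimate[res$contrasts$group == "A"],
               -(cm("A", "BSE") - cm("A", "placebo")), tolerance = 1e-10)
  expect_equal(res$contrasts$estimate[res$contrasts$group == "B"],
               -(cm("B", "BSE") - cm("B", "placebo")), tolerance = 1e-10)
  expect_lt(res$interaction_p, 0.001)
  # group present in a single arm is dropped with a warning
  grp2 <- grp
  grp2[36:40] <- "C"  # C exists only among placebo
  expect_warning(res2 <- interaction_model(d, grp2), "dropped")
  expect_setequal(res2$contrasts$group, c("A", "B"))
})

test_that("responder and remission classification follow their rules exactly", {
  d <- make_trial(c(0.4, 0.3, 0.2, 0.0), c(0.1))
  resp <- classify_responders(d, mode = "fixed", threshold = 0.3)
  expect_equal(sum(resp$pronounced_responder), 2)  # inclusive at 0.3
  # quantile mode: threshold is the top quartile of improvements
  respq <- classify_responders(d, mode = "quantile")
  expect_equal(attr(respq, "threshold"),
               unname(quantile(c(0.4, 0.3, 0.2, 0.0), 0.75)))
  # all-equal improvements: inclusive rule labels everyone a responder
  d_eq <- make_trial(rep(0.2, 4), c(0.1))
  respe <- classify_responders(d_eq, mode = "quantile")
  expect_true(all(respe$pronounced_responder))
  # remission strictly below 6.1
  d2 <- make_trial(c(0.4, 0.3), c(0.1), baseline_glucose = 6.4)
  d2$week12_glucose <- c(6.0, 6.1, 6.3)
  rem <- classify_remission(d2)
  expect_equal(rem$remission, c(TRUE, FALSE))
  # vectorized rule equals element-wise scan
  expect_equal(rem$remission, vapply(rem$week12_glucose,
                                     function(g) g < 6.1, logical(1)))
})

test_that("responder counts agree with a brute-force threshold scan", {
  set.seed(77)
  imp <- rnorm(35, 0.2, 0.63)
  d <- make_trial(imp, rnorm(39, 0, 0.63))
  for (thr in c(0.1, 0.3, 0.5)) {
    resp <- classify_responders(d, threshold = thr)
    expect_equal(sum(resp$pronounced_responder), sum(imp >= thr))
  }
})

test_that("BT2160-by-cluster interaction detects a MARD-only dependence", {
  set.seed(41)
  n <- 3000
  cluster <- sample(c("MARD", "SIRD", "MOD"), n, replace = TRUE)
  log_bt <- rnorm(n, -3.6, 0.25)
  bsa <- rnorm(n, 1.9, 0.15)
  # improvement rises with abundance only in MARD => dglucose falls
  dglu <- rnorm(n, 0, 0.3) - ifelse(cluster == "MARD", 0.8, 0) * (log_bt + 3.6)
  est <- bt2160_cluster_interaction(dglu, exp(log_bt), cluster, bsa)
  expect_lt(est$estimate, -0.5)
  expect_lt(est$p_value, 0.001)
  # null data: no interaction signal
  dglu0 <- rnorm(n, 0, 0.3)
  est0 <- bt2160_cluster_interaction(dglu0, exp(log_bt), cluster, bsa)
  expect_gt(est0$p_value, 0.001)
  # zero abundances handled via pseudocount, not -Inf
  bt <- exp(log_bt)
  bt[1:5] <- 0
  est_pc <- bt2160_cluster_interaction(dglu, bt, cluster, bsa)
  expect_true(is.finite(est_pc$estimate))
})

test_that("median split respects ties-to-lower and the sort-based oracle", {
  imp <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  bt <- c(1, 2, 3, 4, 5, 5, 7, 8, 9, 10)  # median 5, two values at it
  cl <- rep(c("MARD", "SIRD"), 5)
  res <- stratified_by_median(imp, bt, cl)
  med <- median(bt)
  expect_equal(sum(bt > med), res$n[res$stratum == "above"])
  expect_equal(sum(bt <= med), res$n[res$stratum == "below"])
  # symmetric null: both stratum contrasts near zero
  set.seed(52)
  imp0 <- rnorm(400)
  bt0 <- runif(400)
  cl0 <- sample(c("MARD", "MOD"), 400, replace = TRUE)
  res0 <- stratified_by_median(imp0, bt0, cl0)
  expect_true(all(abs(res0$estimate) < 4 * sqrt(2 / 100)))
})

test_that("remission regression returns R2 consistent with its definition", {
  set.seed(61)
  n <- 200
  log_bt <- rnorm(n, -3.6, 0.3)
  ggt <- rnorm(n, 0.7, 0.2)
  prob <- plogis(3 * (log_bt + 3.6) - 5 * (ggt - 0.7))
  rem <- runif(n) < prob
  fit <- remission_model(rem, exp(log_bt), ggt)
  # linear-mode R2 equals squared correlation of fitted and observed
  d <- data.frame(y = as.numeric(rem), log_bt = log_bt, ggt = ggt)
  lmfit <- lm(y ~ log_bt + ggt, data = d)
  expect_equal(fit$r_squared, cor(fitted(lmfit), d$y)^2, tolerance = 1e-10)
  expect_lt(fit$p_values["bt2160"], 0.01)
  # covariates independent of outcome: R2 near zero
  fit0 <- remission_model(sample(rem), exp(log_bt), ggt)
  expect_lt(fit0$r_squared, 0.05)
  expect_error(remission_model(rep(TRUE, 10), exp(log_bt[1:10]), ggt[1:10]),
               "constant")
  # logistic sensitivity returns a pseudo-R2 in [0, 1]
  fitl <- remission_model(rem, exp(log_bt), ggt, family = "logistic")
  expect_true(fitl$r_squared > 0 && fitl$r_squared < 1)
})

test_that("improvement and model change are exact negatives (sign discipline)", {
  d <- make_trial(c(0.4, -0.1, 0.25), c(0.05, 0))
  expect_equal(glycaemic_improvement(d),
               -(d$week12_glucose - d$baseline_glucose))
})
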