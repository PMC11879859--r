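test_that("Bray-Curtis matches hand arithmetic and its bounds", {
  m <- rbind(a = c(1, 0, 3), b = c(2, 1, 1))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0.5)  # 4/8 by hand
  expect_equal(diag(d), c(a = 0, b = 0))
  same <- rbind(x = c(1, 2, 3), y = c(1, 2, 3))
  expect_equal(bray_curtis(same)["x", "y"], 0)
  disjoint <- rbind(x = c(1, 1, 0, 0), y = c(0, 0, 2, 5))
  expect_equal(bray_curtis(disjoint)["x", "y"], 1)
  set.seed(3)
  big <- matrix(rexp(60), 6)
  db <- bray_curtis(big)
  expect_true(all(db >= 0 & db <= 1))
  expect_equal(db, t(db))
  bad <- rbind(x = c(1, 1), y = c(0, 0))
  expect_error(bray_curtis(bad), "all-zero sample.*y")
})

test_that("PCoA reconstructs Euclidean toy distances and orders eigenvalues", {
  set.seed(5)
  pts <- cbind(runif(8), runif(8))
  d <- euclid_dist(pts)
  res <- pcoa(d, n_axes = 2)
  recon <- as.matrix(dist(res$coordinates))
  expect_lt(max(abs(recon - d)), 1e-8)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  expect_true(all(res$proportion_explained > 0))
  # two samples at distance d: one axis, coordinates +/- d/2
  d2 <- matrix(c(0, 0.8, 0.8, 0), 2)
  res2 <- pcoa(d2, n_axes = 1)
  expect_equal(sort(res2$coordinates[, 1]), c(-0.4, 0.4), tolerance = 1e-10)
  expect_warning(pcoa(d2, n_axes = 3), "truncating")
})

test_that("PERMANOVA agrees with exhaustive enumeration and with adonis2", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(6, 0), 3), matrix(rnorm(6, 2), 3))
  d <- euclid_dist(pts)
  g <- rep(c("A", "B"), each = 3)
  ex <- permanova(d, g, exhaustive = TRUE)
  expect_equal(ex$n_perm, choose(6, 3))
  # independent brute-force oracle over all 20 assignments
  splits <- combn(6, 3)
  fs <- apply(splits, 2, function(idx) {
    gg <- rep("B", 6); gg[idx] <- "A"
    bsetrial:::pseudo_f(d^2, gg)
  })
  expect_equal(ex$p_value, mean(fs >= ex$f))
  # pseudo-F equals vegan's adonis2 on the same distances
  ad <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(ex$f, ad$F[1], tolerance = 1e-10)
  # sampled p approximates the exhaustive one
  samp <- permanova(d, g, n_perm = 2000, seed = 7)
  expect_lt(abs(samp$p_value - ex$p_value), 0.03)
  expect_error(permanova(d, rep("A", 6)), "2 groups")
})

test_that("PERMANOVA attains its minimal p on perfectly separated groups", {
  pts <- rbind(matrix(rnorm(20, 0, 0.1), 10), matrix(rnorm(20, 50, 0.1), 10))
  d <- euclid_dist(pts)
  g <- rep(c("A", "B"), each = 10)
  res <- permanova(d, g, n_perm = 199, seed = 1)
  expect_equal(res$p_value, 1 / 200)
})

test_that("gene permutation test matches exhaustive enumeration at n = 8", {
  set.seed(11)
  x <- c(rnorm(4, 0.032, 0.006), rnorm(4, 0.022, 0.006))
  g <- rep(c("high", "low"), each = 4)
  ex <- gene_permutation_test(x, g, exhaustive = TRUE)
  expect_equal(ex$n_perm, choose(8, 4))
  # independent oracle
  splits <- combn(8, 4)
  stats_all <- apply(splits, 2, function(idx) mean(x[idx]) - mean(x[-idx]))
  obs <- mean(x[1:4]) - mean(x[5:8])
  expect_equal(ex$observed, obs)
  expect_equal(ex$p_plain, mean(abs(stats_all) >= abs(obs)))
  # sampled mode approximates; p_value uses add-one, p_plain is the raw share
  samp <- gene_permutation_test(x, g, n_perm = 4000, seed = 3)
  expect_lt(abs(samp$p_plain - ex$p_plain), 0.04)
  expect_equal(samp$p_value, (samp$p_plain * 4000 + 1) / 4001)
  # identical groups: zero statistic, p = 1
  same <- gene_permutation_test(rep(c(1, 2), 4), rep(c("a", "b"), each = 4),
                                n_perm = 200, seed = 1)
  expect_gt(same$p_value, 0.5)
  expect_warning(gene_permutation_test(rep(1, 8), g), "constant")
})

test_that("trial-scale BT2160 strata are usually detected at alpha 0.05", {
  # strata means 0.032 vs 0.022 at roughly the trial's BSE-arm sample size
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    z <- rnorm(35)
    strat <- ifelse(z > 0, "high", "low")
    bt <- exp(-3.64 + 0.234 * z)
    res <- gene_permutation_test(bt, strat, n_perm = 400, seed = s)
    hits <- hits + (res$p_value < 0.05)
  }
  expect_gt(hits, 10)
})

test_that("gene richness counts detected features, monotone in threshold", {
  m <- rbind(s1 = c(0, 5, 0, 2), s2 = c(0, 0, 0, 0))
  expect_equal(gene_richness(m), c(s1 = 2, s2 = 0))
  set.seed(13)
  big <- matrix(rexp(200), 10)
  r <- sapply(c(0, 0.5, 1, 2), function(t) gene_richness(big, t))
  expect_true(all(apply(r, 1, function(x) all(diff(x) <= 0))))
  expect_error(gene_richness(m, -1), ">= 0")
})

test_that("dispersion change detects contraction and matches exhaustive p", {
  set.seed(15)
  pre <- matrix(rnorm(10, 0, 1), 5)
  post <- pre * 0.3  # contracted cloud
  d <- euclid_dist(rbind(pre, post))
  tp <- rep(c("pre", "post"), each = 5)
  res <- dispersion_change(d, tp, n_perm = 500, seed = 2)
  expect_lt(res$statistic, 0)
  expect_lt(res$p_value, 0.1)
  # n = 4: exact enumeration equals the brute-force oracle
  pts <- matrix(c(0, 0, 1, 0, 0.1, 2, 1.1, 2), 4, 2, byrow = TRUE)
  d4 <- euclid_dist(pts)
  tp4 <- c("pre", "pre", "post", "post")
  ex <- dispersion_change(d4, tp4, exhaustive = TRUE)
  splits <- combn(4, 2)
  stats_all <- apply(splits, 2, function(idx) {
    post_i <- setdiff(1:4, idx)
    mean(d4[post_i, post_i][upper.tri(d4[post_i, post_i])]) -
      mean(d4[idx, idx][upper.tri(d4[idx, idx])])
  })
  expect_equal(ex$p_value, mean(abs(stats_all) >= abs(ex$statistic)))
  expect_error(dispersion_change(d4, c("pre", "post", "post", "post")),
               ">= 2 samples")
})
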