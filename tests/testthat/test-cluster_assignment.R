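# Small well-separated blob references keep these tests fast; the full-size
# projection is exercised by the acceptance suite.

make_blobs <- function(n_per, centers, sd = 0.1, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_per * ncol(centers), mean = rep(centers[i, ], each = n_per),
                 sd = sd), n_per)))
  colnames(x) <- paste0("f", seq_len(ncol(centers)))
  list(features = as.data.frame(x),
       latent = rep(seq_len(nrow(centers)), each = n_per))
}

test_that("canonical fit recovers well-separated blob centroids", {
  centers <- rbind(c(0, 0), c(5, 0), c(0, 5), c(5, 5))
  blobs <- make_blobs(100, centers, sd = 0.2, seed = 11)
  m <- fit_canonical_model(blobs$features, k = 4, seed = 1)
  # map true centers into the model's standardized space and match
  mu <- colMeans(blobs$features)
  sdv <- apply(blobs$features, 2, sd)
  truth <- scale(centers, center = mu, scale = sdv)
  d <- as.matrix(dist(rbind(m$centroids, truth)))[1:4, 5:8]
  expect_lt(max(apply(d, 1, min)), 0.1)
  # determinism under seed
  m2 <- fit_canonical_model(blobs$features, k = 4, seed = 1)
  expect_identical(m$centroids, m2$centroids)
})

test_that("k = 1 gives the origin in standardized space; errors are specific", {
  blobs <- make_blobs(30, rbind(c(0, 0), c(4, 4)), seed = 2)
  m1 <- fit_canonical_model(blobs$features, k = 1, seed = 1)
  expect_equal(unname(m1$centroids), matrix(0, 1, 2), tolerance = 1e-10)
  const <- blobs$features
  const$f2 <- 1
  expect_error(fit_canonical_model(const, k = 2), "zero-variance.*f2")
  tiny <- data.frame(f1 = c(1, 1, 1), f2 = c(2, 2, 2))
  expect_error(fit_canonical_model(tiny, k = 2), "distinct|zero-variance")
})

test_that("bootstrap round matches labels back to canonical order", {
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  blobs <- make_blobs(80, centers, sd = 0.2, seed = 5)
  m <- fit_canonical_model(blobs$features, k = 3, seed = 3)
  set.seed(42)
  cents <- replicate(50, bootstrap_round(blobs$features, m, 0.6, restarts = 3),
                     simplify = FALSE)
  # every round's matched centroids sit near the canonical ones
  dev <- sapply(cents, function(cc) max(sqrt(rowSums((cc - m$centroids)^2))))
  expect_lt(max(dev), 0.2)
  # full-sample round reproduces the canonical fit (same optimum)
  set.seed(1)
  full <- bootstrap_round(blobs$features, m, subsample_frac = 1, restarts = 5)
  expect_equal(unname(full), unname(m$centroids), tolerance = 1e-6)
})

test_that("label matching corrects swapped round labels", {
  canonical <- rbind(c(-1, 0), c(1, 0))
  cost_swapped <- rbind(c(4, 0), c(0, 4))  # round centroid 1 is canonical 2
  expect_equal(bsetrial:::hungarian_match(cost_swapped), c(2L, 1L))
  cost_id <- rbind(c(0, 4), c(4, 0))
  expect_equal(bsetrial:::hungarian_match(cost_id), c(1L, 2L))
})

test_that("nearest-centroid assignment matches brute force and breaks ties low", {
  centroids <- rbind(c(-1, 0), c(0, 0.8), c(1, 0))
  scaling <- list(mean = c(f1 = 0, f2 = 0), sd = c(f1 = 1, f2 = 1))
  set.seed(8)
  pts <- data.frame(f1 = runif(40, -2, 2), f2 = runif(40, -2, 2))
  colnames(centroids) <- c("f1", "f2")
  idx <- assign_nearest(pts, centroids, scaling)
  brute <- apply(as.matrix(pts), 1, function(p)
    which.min(colSums((t(centroids) - p)^2)))
  expect_equal(as.integer(idx), as.integer(brute))
  # participant exactly at a centroid
  at2 <- assign_nearest(data.frame(f1 = 0, f2 = 0.8), centroids, scaling)
  expect_equal(as.integer(at2), 2L)
  # equidistant to clusters 1 and 3 (both nearer than 2): tie goes low
  tie <- assign_nearest(data.frame(f1 = 0, f2 = -0.5), centroids, scaling)
  expect_equal(as.integer(tie), 1L)
  expect_equal(attr(tie, "n_ties"), 1L)
  expect_error(assign_nearest(data.frame(f1 = NA, f2 = 0), centroids, scaling),
               "missing feature")
})

test_that("bootstrap assignment conserves counts and scores stable points as 1", {
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  blobs <- make_blobs(60, centers, sd = 0.2, seed = 6)
  parts <- as.data.frame(rbind(centers, c(3, 3)))
  colnames(parts) <- c("f1", "f2")
  res <- run_bootstrap_assignment(blobs$features, parts, k = 3, B = 50,
                                  seed = 9, restarts = 3)
  expect_true(all(rowSums(res$counts) == 50))
  expect_true(all(res$assignments$alignment_score > 0 &
                    res$assignments$alignment_score <= 1))
  # blob-center participants are unambiguous: perfect alignment
  expect_equal(res$assignments$alignment_score[1:3], rep(1, 3))
  # determinism under seed
  res2 <- run_bootstrap_assignment(blobs$features, parts, k = 3, B = 50,
                                   seed = 9, restarts = 3)
  expect_identical(res$counts, res2$counts)
})

test_that("oracle equivalence: tiny k=2 reference vs exhaustive nearest-centroid", {
  ref <- data.frame(f1 = c(0, 0.2, -0.1, 5.1, 5.0, 4.9))
  m <- fit_canonical_model(ref, k = 2, seed = 4)
  pts <- data.frame(f1 = seq(-1, 6, by = 0.5))
  idx <- assign_nearest(pts, m$centroids, m$scaling)
  z <- (pts$f1 - m$scaling$mean["f1"]) / m$scaling$sd["f1"]
  brute <- ifelse(abs(z - m$centroids[1, "f1"]) <=
                    abs(z - m$centroids[2, "f1"]), 1L, 2L)
  expect_equal(as.integer(idx), as.integer(brute))
})

test_that("alignment score degrades toward 1/k as separation vanishes", {
  overlap <- make_blobs(150, rbind(c(0, 0), c(0.05, 0)), sd = 1, seed = 12)
  res <- run_bootstrap_assignment(overlap$features, overlap$features[1:40, ],
                                  k = 2, B = 60, seed = 2, restarts = 3)
  # indistinguishable clusters: the split is arbitrary, so stability drops
  # well below the separated case (subsample correlation keeps it above 1/k)
  expect_lt(mean(res$assignments$alignment_score), 0.95)
  sep <- make_blobs(150, rbind(c(0, 0), c(8, 0)), sd = 0.3, seed = 12)
  res2 <- run_bootstrap_assignment(sep$features, sep$features[1:40, ],
                                   k = 2, B = 60, seed = 2, restarts = 3)
  expect_gt(mean(res2$assignments$alignment_score), 0.99)
  expect_lt(mean(res$assignments$alignment_score),
            mean(res2$assignments$alignment_score))
})

test_that("label hints name clusters after the matching specs", {
  rc <- generate_reference_cohort(600, seed = 19)
  m <- fit_canonical_model(rc$features, k = 4, seed = 5,
                           label_hints = default_hints())
  expect_setequal(m$labels, c("MARD", "SIRD", "MOD", "SIDD"))
  idx <- assign_nearest(rc$features, m$centroids, m$scaling)
  expect_gt(recovery_rate(m$labels[idx], rc$latent), 0.95)
})
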