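# Bootstrap cluster projection: standardize clustering features against a
# reference cohort, k-means the reference (and 60% bootstrap subsamples of
# it), match each round's centroids to the canonical ones by minimum-cost
# bipartite assignment, project trial participants onto the nearest centroid,
# and score per-participant assignment stability across rounds.

default_feature_names <- c("age", "bmi", "glucose", "c_peptide", "hba1c")

# exact minimum-cost bipartite assignment by permutation enumeration (k <= 8)
hungarian_match <- function(cost) {
  k <- nrow(cost)
  stopifnot(k == ncol(cost))
  if (k > 8) stop("label matching supports k <= 8")
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL
  best_cost <- Inf
  for (p in perms(seq_len(k))) {
    cst <- sum(cost[cbind(seq_len(k), p)])
    if (cst < best_cost) {
      best_cost <- cst
      best <- p
    }
  }
  best  # best[i] = column (canonical cluster) assigned to row i
}

# greedy k-means++ initialization followed by Lloyd iterations, best of
# `restarts` seeded starts by total within-cluster sum of squares
kmeanspp_lloyd <- function(x, k, restarts = 10, iter_max = 300) {
  n <- nrow(x)
  if (nrow(unique(x)) < k)
    stop("fewer distinct points (", nrow(unique(x)), ") than k = ", k)
  n_cand <- 2 + ceiling(log(k))
  init_pp <- function() {
    centers <- x[sample.int(n, 1), , drop = FALSE]
    d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
    while (nrow(centers) < k) {
      if (all(d2 == 0)) stop("fewer distinct points than k")
      cand <- sample.int(n, min(n_cand, n), prob = pmax(d2, 0) + 1e-300)
      # greedy: candidate that most reduces the total potential
      red <- vapply(cand, function(j) {
        dj <- rowSums((x - matrix(x[j, ], n, ncol(x), byrow = TRUE))^2)
        sum(pmin(d2, dj))
      }, numeric(1))
      j <- cand[which.min(red)]
      centers <- rbind(centers, x[j, , drop = FALSE])
      dj <- rowSums((x - matrix(x[j, ], n, ncol(x), byrow = TRUE))^2)
      d2 <- pmin(d2, dj)
    }
    centers
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    km <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = init_pp(),
                                     iter.max = iter_max,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed on all restarts")
  best
}

#' Fit the canonical cluster model on a reference cohort
#'
#' Standardizes the clustering features by the reference cohort's mean and SD
#' (z-scores), runs k-means (greedy k-means++ initialization, Lloyd
#' iterations, multiple restarts), and returns the canonical centroids with
#' the standardization parameters that define the projection. Centroids are
#' put in a deterministic canonical order: when `label_hints` (named matrix
#' of cluster centres in natural units, e.g. built from
#' [default_cluster_specs()]) is supplied, centroids are matched to the hints
#' by minimum-cost assignment and take their names and order; otherwise they
#' are ordered lexicographically by coordinates and named `cluster_1..k`.
#'
#' @param reference Data.frame/matrix of clustering features, no missing
#'   values.
#' @param k Number of clusters (default 4: MARD/SIRD/MOD/SIDD-like).
#' @param feature_names Features used (default: the columns of `reference`).
#' @param seed Integer seed.
#' @param restarts k-means restarts per fit.
#' @param label_hints Optional named matrix (rows = cluster labels, columns =
#'   features, natural units) used to name the clusters.
#' @return Object of class `"cluster_model"`: list with `k`, `centroids`
#'   (k x p, standardized space), `labels`, `scaling` (`mean`, `sd`),
#'   `feature_names`.
#' @export
fit_canonical_model <- function(reference, k = 4, feature_names = NULL,
                                seed = 1, restarts = 10, label_hints = NULL) {
  x <- as.matrix(as.data.frame(reference))
  if (is.null(feature_names)) feature_names <- colnames(x)
  x <- x[, feature_names, drop = FALSE]
  if (anyNA(x)) stop("reference has missing feature values")
  if (nrow(x) < k) stop("reference must have at least k rows")
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  zero <- sdv == 0
  if (any(zero))
    stop("zero-variance feature(s): ",
         paste(feature_names[zero], collapse = ", "))
  z <- scale(x, center = mu, scale = sdv)
  set.seed(seed)
  km <- kmeanspp_lloyd(z, k, restarts = restarts)
  centroids <- km$centers
  if (!is.null(label_hints)) {
    h <- as.matrix(label_hints)[, feature_names, drop = FALSE]
    if (nrow(h) != k) stop("label_hints must have k rows")
    hz <- scale(h, center = mu, scale = sdv)
    cost <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j)
      sum((centroids[i, ] - hz[j, ])^2)))
    match <- hungarian_match(cost)  # match[i] = hint row for centroid i
    ord <- order(match)
    centroids <- centroids[ord, , drop = FALSE]
    labels <- rownames(h)
  } else {
    ord <- do.call(order, as.data.frame(round(centroids, 10)))
    centroids <- centroids[ord, , drop = FALSE]
    labels <- paste0("cluster_", seq_len(k))
  }
  rownames(centroids) <- labels
  structure(list(k = k, centroids = centroids, labels = labels,
                 scaling = list(mean = mu, sd = sdv),
                 feature_names = feature_names),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Canonical cluster model: k =", x$k, "over",
      paste(x$feature_names, collapse = ", "), "\n")
  print(round(x$centroids, 3))
  invisible(x)
}

#' One bootstrap clustering round
#'
#' Draws `floor(subsample_frac * n)` reference rows without replacement,
#' k-means-clusters the subsample in the model's standardized space, and
#' matches the round's centroids to the canonical centroids by minimum-cost
#' bipartite assignment so cluster identity is stable across rounds. Uses the
#' current RNG state (seed management belongs to
#' [run_bootstrap_assignment()]).
#'
#' @param reference Reference feature table (same features as the model).
#' @param model A [fit_canonical_model()] result.
#' @param subsample_frac Subsampling fraction in (0, 1]; default 0.6.
#' @param restarts k-means restarts for the round.
#' @param max_retries Redraws allowed when a subsample has < k distinct
#'   points.
#' @return k x p matrix of label-matched centroids in standardized space.
#' @export
bootstrap_round <- function(reference, model, subsample_frac = 0.6,
                            restarts = 10, max_retries = 10) {
  stopifnot(inherits(model, "cluster_model"),
            subsample_frac > 0, subsample_frac <= 1)
  x <- as.matrix(as.data.frame(reference))[, model$feature_names,
                                           drop = FALSE]
  n <- nrow(x)
  m <- floor(subsample_frac * n)
  if (m < model$k) stop("subsample size ", m, " below k = ", model$k)
  z <- scale(x, center = model$scaling$mean, scale = model$scaling$sd)
  for (try in seq_len(max_retries)) {
    idx <- sample.int(n, m)
    sub <- z[idx, , drop = FALSE]
    if (nrow(unique(sub)) < model$k) next
    km <- kmeanspp_lloyd(sub, model$k, restarts = restarts)
    cost <- outer(seq_len(model$k), seq_len(model$k),
                  Vectorize(function(i, j)
                    sum((km$centers[i, ] - model$centroids[j, ])^2)))
    match <- hungarian_match(cost)  # match[i] = canonical slot of round centroid i
    out <- km$centers
    out[match, ] <- km$centers
    rownames(out) <- model$labels
    return(out)
  }
  stop("subsample had fewer distinct points than k after ", max_retries,
       " retries")
}

#' Assign participants to nearest centroids
#'
#' Standardizes participant features with the model's reference scaling and
#' assigns each participant to the cluster whose centroid is nearest in
#' Euclidean distance. Exact ties are broken toward the lowest canonical
#' cluster index; the number of tied assignments is recorded in the
#' `n_ties` attribute.
#'
#' @param participants Feature table (rows = participants).
#' @param centroids k x p centroid matrix in standardized space.
#' @param scaling List with `mean` and `sd` (from the same model).
#' @return Integer vector of cluster indices with attribute `n_ties`.
#' @export
assign_nearest <- function(participants, centroids, scaling) {
  x <- as.matrix(as.data.frame(participants))[, colnames(centroids),
                                              drop = FALSE]
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)
    stop("missing feature '", colnames(x)[bad[1, 2]], "' for participant ",
         bad[1, 1])
  }
  z <- scale(x, center = scaling$mean, scale = scaling$sd)
  d2 <- outer(rowSums(z^2), rep(1, nrow(centroids))) -
    2 * z %*% t(centroids) +
    outer(rep(1, nrow(z)), rowSums(centroids^2))
  idx <- apply(d2, 1, which.min)  # which.min takes the lowest index on ties
  ties <- apply(d2, 1, function(r) sum(abs(r - min(r)) < 1e-12) > 1)
  attr(idx, "n_ties") <- sum(ties)
  idx
}

#' Bootstrap cluster assignment with stability scores
#'
#' The full projection procedure: fit the canonical model on the reference
#' cohort, then repeat `B` bootstrap rounds (60% subsample, k-means, label
#' matching) and assign every participant to the nearest round centroids,
#' accumulating per-cluster assignment counts. The modal cluster is the
#' participant's label (ties to the lowest canonical index, flagged) and the
#' cluster alignment score is the fraction of rounds agreeing with the mode,
#' in (0, 1].
#'
#' @param reference Reference cohort feature table.
#' @param participants Participant feature table (same features).
#' @param k Number of clusters.
#' @param B Number of bootstrap rounds.
#' @param subsample_frac Subsample fraction per round (default 0.6).
#' @param seed Integer seed (governs the canonical fit and all rounds).
#' @param restarts k-means restarts per fit.
#' @param label_hints Optional cluster-naming hints, see
#'   [fit_canonical_model()].
#' @return Object of class `"assignment_result"`: list with `assignments`
#'   (data.frame: one row per participant with per-cluster counts,
#'   `modal_label`, `alignment_score`, `modal_tie`), `counts` (matrix),
#'   `model`, `B`.
#' @export
run_bootstrap_assignment <- function(reference, participants, k = 4, B = 1000,
                                     subsample_frac = 0.6, seed = 1,
                                     restarts = 10, label_hints = NULL) {
  stopifnot(B >= 1)
  model <- fit_canonical_model(reference, k = k, seed = seed,
                               restarts = restarts, label_hints = label_hints)
  np <- nrow(as.data.frame(participants))
  counts <- matrix(0L, np, k, dimnames = list(NULL, model$labels))
  for (b in seq_len(B)) {
    cent <- bootstrap_round(reference, model, subsample_frac = subsample_frac,
                            restarts = restarts)
    idx <- assign_nearest(participants, cent, model$scaling)
    counts[cbind(seq_len(np), idx)] <- counts[cbind(seq_len(np), idx)] + 1L
  }
  modal_idx <- apply(counts, 1, which.max)
  modal_tie <- apply(counts, 1, function(r) sum(r == max(r)) > 1)
  assignments <- data.frame(
    counts, modal_label = model$labels[modal_idx],
    alignment_score = apply(counts, 1, max) / B,
    modal_tie = modal_tie,
    stringsAsFactors = FALSE, check.names = FALSE)
  structure(list(assignments = assignments, counts = counts, model = model,
                 B = B),
            class = "assignment_result")
}

#' Extract the clustering feature table from a trial dataset
#'
#' Maps the baseline columns of a [trial_schema()] table to the clustering
#' feature names (age, BMI, fasting glucose, C-peptide, HbA1c).
#'
#' @param dataset A trial dataset.
#' @return Data.frame of clustering features.
#' @export
clustering_features <- function(dataset) {
  data.frame(age = dataset$age,
             bmi = dataset$baseline_bmi,
             glucose = dataset$baseline_glucose,
             c_peptide = dataset$baseline_c_peptide,
             hba1c = dataset$baseline_hba1c)
}
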