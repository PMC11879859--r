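# Community-level and gene-level microbiome statistics: Bray-Curtis
# dissimilarity, principal coordinates, one-factor PERMANOVA, the gene
# (BT2160) permutation test, gene richness, and a within-group dispersion
# change test. Permutation p-values use the add-one convention
# (1 + b) / (1 + m) so that p is never 0; the gene test additionally reports
# the plain proportion-of-permutations variant.

#' Bray-Curtis dissimilarity matrix
#'
#' \deqn{d(x, y) = \sum_i |x_i - y_i| \; / \; \sum_i (x_i + y_i)}
#' computed over features for every sample pair (rows are samples). Values lie
#' in `[0, 1]`; note Bray-Curtis is a semimetric (the triangle inequality is
#' not guaranteed).
#'
#' @param table Numeric matrix or data.frame, samples x features, entries >= 0.
#' @return Symmetric `n x n` matrix with zero diagonal, sample ids as dimnames.
#' @examples
#' bray_curtis(rbind(a = c(1, 0, 3), b = c(2, 1, 1)))  # 0.5
#' @export
bray_curtis <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0)) stop("abundance table has negative entries")
  tot <- rowSums(m)
  if (any(tot == 0)) {
    bad <- rownames(m)[tot == 0]
    if (is.null(bad)) bad <- which(tot == 0)
    stop("all-zero sample(s): ", paste(bad, collapse = ", "))
  }
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  diag(d) <- 0
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centres the squared dissimilarities (Gower transformation) and
#' eigendecomposes, scaling each coordinate axis by the square root of its
#' eigenvalue. Axes with non-positive eigenvalues carry no real coordinates
#' and are dropped (negative eigenvalues are still reported, as is usual for
#' semimetrics such as Bray-Curtis).
#'
#' @param d Symmetric dissimilarity matrix (e.g. from [bray_curtis()]).
#' @param n_axes Number of coordinate axes requested.
#' @return List with `coordinates` (n x k), `eigenvalues` (all, non-increasing)
#'   and `proportion_explained` (relative to the positive eigenvalue total).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 samples")
  eig <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1,
                                          eig = TRUE))
  ev <- eig$eig
  pos <- sum(ev > 1e-12)
  if (n_axes > pos) {
    warning("only ", pos, " positive eigenvalue(s); truncating axes")
    n_axes <- pos
  }
  coords <- eig$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  list(coordinates = coords,
       eigenvalues = sort(ev, decreasing = TRUE),
       proportion_explained = sort(ev, decreasing = TRUE)[seq_len(n_axes)] /
         sum(ev[ev > 0]))
}

# One-factor pseudo-F from a distance matrix:
# SST = sum_{i<j} d_ij^2 / n; SSW pooled within groups; F = (SSA/(a-1)) / (SSW/(n-a))
pseudo_f <- function(d2, groups) {
  n <- nrow(d2)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      dg <- d2[idx, idx]
      ssw <- ssw + sum(dg[upper.tri(dg)]) / length(idx)
    }
  }
  a <- length(unique(groups))
  ((sst - ssw) / (a - 1)) / (ssw / (n - a))
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a dissimilarity matrix:
#' the pseudo-F statistic is computed from between/within sums of squared
#' dissimilarities, and significance from random permutations of the group
#' labels with the add-one convention
#' \eqn{p = (1 + \#\{F^{perm} \ge F^{obs}\}) / (1 + n_{perm})}.
#'
#' With `exhaustive = TRUE` (two groups only, small n) every distinct
#' assignment of the group sizes to samples is enumerated instead and the
#' p-value is the exact proportion of assignments with \eqn{F \ge F^{obs}}
#' (the observed assignment included; no add-one correction is needed).
#'
#' @param d Symmetric dissimilarity matrix.
#' @param groups Group label per sample (>= 2 groups, each nonempty).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param exhaustive Enumerate all two-group assignments instead of sampling.
#' @return List with `f` (pseudo-F), `p_value`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 10000, seed = 1,
                      exhaustive = FALSE) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  stopifnot(nrow(d) == length(groups))
  if (length(unique(groups)) < 2) stop("need at least 2 groups")
  d2 <- d^2
  f_obs <- pseudo_f(d2, groups)
  if (exhaustive) {
    lev <- unique(groups)
    if (length(lev) != 2)
      stop("exhaustive enumeration supports exactly 2 groups")
    n <- length(groups)
    n1 <- sum(groups == lev[1])
    splits <- utils::combn(n, n1)
    fs <- apply(splits, 2, function(idx) {
      g <- rep(lev[2], n); g[idx] <- lev[1]
      pseudo_f(d2, g)
    })
    return(list(f = f_obs, p_value = mean(fs >= f_obs),
                n_perm = ncol(splits)))
  }
  set.seed(seed)
  b <- 0L
  for (i in seq_len(n_perm)) {
    if (pseudo_f(d2, sample(groups)) >= f_obs) b <- b + 1L
  }
  list(f = f_obs, p_value = (1 + b) / (1 + n_perm), n_perm = n_perm)
}

#' Two-group permutation test for gene abundance
#'
#' Tests a difference in mean abundance between two groups by permuting the
#' group labels. The default is two-sided on the absolute mean difference; the
#' one-sided option counts permuted differences at least as large as the
#' observed signed difference. Ties count as extreme (`>=`). Two p-value
#' conventions are returned: `p_value` with the add-one correction
#' (never zero) and `p_plain`, the raw proportion of permutation statistics at
#' least as extreme as the observed one.
#'
#' @param abundance Numeric per-sample abundances.
#' @param groups Two-level label per sample.
#' @param n_perm Number of permutations (default 10000).
#' With `exhaustive = TRUE` (small n) every distinct split of the sample into
#' the two group sizes is enumerated; `p_plain` is then the exact proportion
#' of splits at least as extreme as the observed one and `p_value` equals it
#' (the observed split is part of the enumeration, so p can never be 0).
#'
#' @param alternative `"two.sided"` (default) or `"greater"` (on the signed
#'   group-1-minus-group-2 difference).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all splits instead of sampling.
#' @return List with `observed` (group-1 mean minus group-2 mean), `p_value`,
#'   `p_plain`, `n_perm`.
#' @export
gene_permutation_test <- function(abundance, groups, n_perm = 10000,
                                  alternative = c("two.sided", "greater"),
                                  seed = 1, exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  abundance <- as.numeric(abundance)
  groups <- as.character(groups)
  stopifnot(length(abundance) == length(groups))
  lev <- unique(groups)
  if (length(lev) != 2) stop("need exactly 2 groups")
  if (stats::sd(abundance) == 0) {
    warning("constant abundance: test has no power, p = 1")
    return(list(observed = 0, p_value = 1, p_plain = 1, n_perm = n_perm))
  }
  g1 <- groups == lev[1]
  obs <- mean(abundance[g1]) - mean(abundance[!g1])
  n1 <- sum(g1)
  n <- length(abundance)
  stat <- function(lab1) mean(abundance[lab1]) - mean(abundance[!lab1])
  if (exhaustive) {
    splits <- utils::combn(n, n1)
    perm <- apply(splits, 2, function(idx) {
      lab1 <- logical(n); lab1[idx] <- TRUE
      stat(lab1)
    })
    b <- if (alternative == "two.sided") sum(abs(perm) >= abs(obs))
         else sum(perm >= obs)
    p <- b / ncol(splits)
    return(list(observed = obs, p_value = p, p_plain = p,
                n_perm = ncol(splits)))
  }
  set.seed(seed)
  perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n, n1)
    lab1 <- logical(n); lab1[idx] <- TRUE
    perm[i] <- stat(lab1)
  }
  b <- if (alternative == "two.sided") sum(abs(perm) >= abs(obs))
       else sum(perm >= obs)
  list(observed = obs,
       p_value = (1 + b) / (1 + n_perm),
       p_plain = b / n_perm,
       n_perm = n_perm)
}

#' Gene richness per sample
#'
#' Number of features detected above a threshold in each sample.
#'
#' @param table Numeric matrix, samples x features.
#' @param detection_threshold Detection cutoff (strictly greater-than;
#'   default 0).
#' @return Named integer vector of per-sample richness.
#' @export
gene_richness <- function(table, detection_threshold = 0) {
  if (detection_threshold < 0) stop("detection_threshold must be >= 0")
  m <- as.matrix(table)
  rowSums(m > detection_threshold)
}

mean_within_dissim <- function(d, idx) {
  if (length(idx) < 2) stop("need >= 2 samples to compute within-group dissimilarity")
  dg <- d[idx, idx]
  mean(dg[upper.tri(dg)])
}

#' Within-group dissimilarity change between timepoints
#'
#' For one group of samples measured at two timepoints, the statistic is the
#' mean pairwise dissimilarity among post samples minus that among pre
#' samples (negative = the group contracted after treatment). Significance is
#' assessed by permuting the timepoint labels within the group; the two-sided
#' add-one p-value is returned.
#'
#' @param d Symmetric dissimilarity matrix over the group's samples.
#' @param timepoint Two-level timepoint label per sample. Labels
#'   `"pre"`/`"post"` (or `"baseline"`/anything) are recognised; otherwise
#'   set `pre` explicitly.
#' @param pre The label denoting the earlier timepoint (default: `"pre"` or
#'   `"baseline"` when present, else the alphabetically first label).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param exhaustive Enumerate all timepoint relabellings instead of
#'   sampling (exact p, observed labelling included).
#' @return List with `statistic` (post minus pre mean within-dissimilarity),
#'   `p_value`, `n_perm`.
#' @export
dispersion_change <- function(d, timepoint, pre = NULL, n_perm = 10000,
                              seed = 1, exhaustive = FALSE) {
  d <- as.matrix(d)
  timepoint <- as.character(timepoint)
  stopifnot(nrow(d) == length(timepoint))
  lev <- sort(unique(timepoint))
  if (length(lev) != 2) stop("need exactly 2 timepoints")
  if (is.null(pre)) {
    pre <- if ("pre" %in% lev) "pre"
           else if ("baseline" %in% lev) "baseline"
           else lev[1]
  }
  if (!pre %in% lev) stop("pre label '", pre, "' not among timepoints")
  lev <- c(pre, setdiff(lev, pre))
  if (min(table(timepoint)) < 2)
    stop("need >= 2 samples at each timepoint")
  stat <- function(tp) {
    mean_within_dissim(d, which(tp == lev[2])) -
      mean_within_dissim(d, which(tp == lev[1]))
  }
  obs <- stat(timepoint)
  if (exhaustive) {
    n <- length(timepoint)
    n1 <- sum(timepoint == lev[1])
    splits <- utils::combn(n, n1)
    stats_all <- apply(splits, 2, function(idx) {
      tp <- rep(lev[2], n); tp[idx] <- lev[1]
      stat(tp)
    })
    return(list(statistic = obs,
                p_value = mean(abs(stats_all) >= abs(obs)),
                n_perm = ncol(splits)))
  }
  set.seed(seed)
  b <- 0L
  for (i in seq_len(n_perm)) {
    if (abs(stat(sample(timepoint))) >= abs(obs)) b <- b + 1L
  }
  list(statistic = obs, p_value = (1 + b) / (1 + n_perm), n_perm = n_perm)
}
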