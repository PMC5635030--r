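# Ecological distances, PERMANOVA, PCA, and distance-based redundancy
# analysis (CAP).

#' Between-sample dissimilarity matrix
#'
#' Bray-Curtis (via [vegan::vegdist()]) on the abundances as given, or
#' Jensen-Shannon divergence on per-sample renormalized profiles with a
#' pseudocount guard. JSD uses the natural logarithm (maximum log 2);
#' `sqrt = TRUE` returns its metric square root.
#'
#' @param m feature-by-sample abundance matrix.
#' @param metric `"bray_curtis"` or `"jensen_shannon"`.
#' @param pseudocount added to every cell before renormalization for JSD.
#' @param sqrt return the square-root (metric) form of JSD.
#' @return symmetric sample-by-sample distance matrix with zero diagonal.
#' @export
distance_matrix <- function(m, metric = c("bray_curtis", "jensen_shannon"),
                            pseudocount = 1e-9, sqrt = FALSE) {
  assert_abundance(m)
  metric <- match.arg(metric)
  if (any(colSums(m) == 0)) stop_input("samples with zero total abundance")
  if (metric == "bray_curtis") {
    d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  } else {
    p <- sweep(m + pseudocount, 2, colSums(m + pseudocount), "/")
    n <- ncol(p)
    d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
    xlogx <- function(v) ifelse(v > 0, v * log(v), 0)
    H <- colSums(xlogx(p))             # negative entropy per sample
    for (i in seq_len(n - 1L)) {
      mi <- (p[, i] + p[, (i + 1L):n, drop = FALSE]) / 2
      jsd <- colSums(xlogx(mi)) * (-1) + (H[i] + H[(i + 1L):n]) / 2
      d[i, (i + 1L):n] <- d[(i + 1L):n, i] <- pmax(jsd, 0)
    }
    if (sqrt) d <- base::sqrt(d)
  }
  diag(d) <- 0
  d
}

permanova_F <- function(d2, groups) {
  n <- length(groups)
  k <- nlevels(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (lv in levels(groups)) {
    ix <- which(groups == lv)
    if (length(ix) > 1L) {
      sub <- d2[ix, ix]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(ix)
    }
  }
  ss_among <- ss_total - ss_within
  list(F = (ss_among / (k - 1)) / (ss_within / (n - k)),
       r2 = ss_among / ss_total)
}

#' Permutational multivariate analysis of variance
#'
#' Pseudo-F from among/within sums of squared distances, with a permutation
#' p-value p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm); 999 permutations by
#' default, so the smallest attainable p is 0.001.
#'
#' @param d symmetric distance matrix (samples x samples).
#' @param labels sample factor with >= 2 levels, each holding >= 2 samples.
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed.
#' @param factor_id label echoed in the result.
#' @return list of class `permanova_result`: `factor_id`, `pseudo_F`,
#'   `r_squared`, `p_value`, `n_perm`.
#' @export
permanova <- function(d, labels, n_perm = 999L, seed = 1L,
                      factor_id = "factor") {
  d <- as.matrix(d)
  groups <- droplevels(as.factor(labels))
  if (nlevels(groups) < 2L) stop_input("labels must have at least 2 levels")
  if (any(table(groups) < 2L)) stop_input("every level needs >= 2 samples")
  if (length(groups) != nrow(d)) stop_input("labels do not match the matrix")
  d2 <- d * d
  obs <- permanova_F(d2, groups)
  eps <- 1e-12
  with_seed(seed, {
    hits <- sum(vapply(seq_len(n_perm), function(i)
      permanova_F(d2, sample(groups))$F >= obs$F - eps, NA))
    structure(list(factor_id = factor_id, pseudo_F = obs$F,
                   r_squared = obs$r2,
                   p_value = (1 + hits) / (1 + n_perm),
                   n_perm = n_perm),
              class = "permanova_result")
  })
}

#' Principal component analysis of an abundance profile
#'
#' Centered (unscaled) PCA over samples, with a fixed sign convention: on
#' each component the largest-magnitude feature loading is made positive.
#'
#' @param m feature-by-sample abundance matrix (>= 2 features, >= 2 samples).
#' @return list with `scores` (samples x PCs), `loadings` (features x PCs)
#'   and `explained_variance` (fractions).
#' @export
pca_ordination <- function(m) {
  assert_abundance(m)
  if (nrow(m) < 2L || ncol(m) < 2L) stop_input("need >= 2 features and samples")
  X <- t(m)
  if (all(apply(X, 2, var) == 0)) stop_input("matrix has zero variance")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2
  list(scores = pc$x, loadings = pc$rotation,
       explained_variance = ev / sum(ev))
}

#' Distance-based redundancy analysis (CAP)
#'
#' Principal-coordinate embedding of the distance matrix (axes with negative
#' eigenvalues are dropped and the discarded inertia reported), followed by
#' redundancy analysis on the group indicator: the PCoA coordinates are
#' projected onto the label design, and constrained axes are the principal
#' axes of the fitted values. Feature weights, when a feature matrix is
#' supplied, are post-hoc correlations of each feature with the constrained
#' scores.
#'
#' @param d symmetric distance matrix.
#' @param labels sample factor (>= 2 levels, >= 2 samples per level).
#' @param features optional feature-by-sample matrix for post-hoc weights.
#' @return list with `scores` (samples x constrained axes), `eigenvalues`,
#'   `centroids` (per level), `neg_inertia_discarded` and `feature_weights`.
#' @export
dbrda <- function(d, labels, features = NULL) {
  d <- as.matrix(d)
  groups <- droplevels(as.factor(labels))
  if (nlevels(groups) < 2L) stop_input("labels must have at least 2 levels")
  if (any(table(groups) < 2L)) stop_input("every level needs >= 2 samples")
  n <- nrow(d)
  if (length(groups) != n) stop_input("labels do not match the matrix")

  # Gower double-centering
  A <- -0.5 * d * d
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(eg$values)) * 1e-10
  pos <- eg$values > tol
  neg_inertia <- -sum(eg$values[eg$values < -tol])
  Y <- eg$vectors[, pos, drop = FALSE] %*% diag(sqrt(eg$values[pos]),
                                                sum(pos))

  X <- model.matrix(~groups)[, -1, drop = FALSE]
  X <- scale(X, center = TRUE, scale = FALSE)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  Yhat <- H %*% Y
  sv <- svd(Yhat)
  nax <- min(nlevels(groups) - 1L, sum(sv$d > max(sv$d) * 1e-8))
  scores <- Y %*% sv$v[, seq_len(nax), drop = FALSE]
  rownames(scores) <- rownames(d)
  colnames(scores) <- sprintf("CAP%d", seq_len(nax))
  for (j in seq_len(nax)) {                 # sign convention
    i <- which.max(abs(scores[, j]))
    if (scores[i, j] < 0) scores[, j] <- -scores[, j]
  }
  centroids <- apply(scores, 2, function(s) tapply(s, groups, mean))
  fw <- NULL
  if (!is.null(features)) {
    assert_abundance(features)
    fw <- suppressWarnings(cor(t(features), scores, method = "spearman"))
  }
  list(scores = scores,
       eigenvalues = (sv$d^2)[seq_len(nax)],
       centroids = centroids,
       neg_inertia_discarded = neg_inertia,
       feature_weights = fw)
}
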