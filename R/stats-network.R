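# Spearman co-occurrence networks and permutation-tested correlations.

network_weight_class <- function(cc) {
  a <- abs(cc)
  ifelse(a >= 0.7, "thick", ifelse(a >= 0.5, "medium", "thin"))
}

#' Spearman co-occurrence network between features
#'
#' All unordered feature pairs whose Spearman correlation across the chosen
#' samples reaches `cc_min` in absolute value become edges, signed and
#' banded by |cc| the way co-abundance networks are usually drawn: thin
#' \[0.3, 0.5), medium \[0.5, 0.7), thick >= 0.7. Case and control networks
#' are obtained by passing the respective sample subset.
#'
#' @param m feature-by-sample abundance matrix.
#' @param sample_subset sample ids (or logical/integer index) to use;
#'   `NULL` = all samples.
#' @param cc_min absolute-correlation threshold for emitting an edge.
#' @return data.frame: `feature_a`, `feature_b` (lexicographic order within
#'   each pair), `cc`, `sign` (positive/negative), `weight_class`.
#' @export
cooccurrence_network <- function(m, sample_subset = NULL, cc_min = 0.3) {
  assert_abundance(m)
  if (!is.null(sample_subset)) m <- m[, sample_subset, drop = FALSE]
  if (ncol(m) < 3L) stop_input("at least 3 samples are required")
  if (nrow(m) < 2L)
    return(data.frame(feature_a = character(0), feature_b = character(0),
                      cc = numeric(0), sign = character(0),
                      weight_class = character(0)))
  m <- m[order(rownames(m)), , drop = FALSE]
  cc <- suppressWarnings(cor(t(m), method = "spearman"))
  cc[is.na(cc)] <- 0                     # constant features: no edge
  idx <- which(upper.tri(cc) & abs(cc) >= cc_min, arr.ind = TRUE)
  out <- data.frame(feature_a = rownames(cc)[idx[, 1]],
                    feature_b = rownames(cc)[idx[, 2]],
                    cc = cc[idx], stringsAsFactors = FALSE)
  out$sign <- ifelse(out$cc >= 0, "positive", "negative")
  out$weight_class <- network_weight_class(out$cc)
  out[order(out$feature_a, out$feature_b), , drop = FALSE]
}

#' Write a co-occurrence edge list as GraphML
#'
#' @param edges edge data.frame from [cooccurrence_network()].
#' @param path output file path.
#' @export
write_network_graphml <- function(edges, path) {
  g <- igraph::graph_from_data_frame(edges[, c("feature_a", "feature_b")],
                                     directed = FALSE)
  igraph::E(g)$cc <- edges$cc
  igraph::E(g)$sign <- edges$sign
  igraph::E(g)$weight_class <- edges$weight_class
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Spearman correlation with a label-permutation p-value
#'
#' Spearman correlation (midranks for ties) with significance from a
#' permutation null: one vector is randomly permuted `n_perm` times and
#' p = (1 + #\{|cc_perm| >= |cc_obs|\}) / (1 + n_perm), so p is never 0.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return list with `cc` and `p_value`.
#' @export
spearman_permutation <- function(x, y, n_perm = 1000L, seed = 1L) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop_input("at least 4 complete pairs are required")
  if (var(x) == 0 || var(y) == 0)
    stop_input("Spearman correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  cc <- cor(rx, ry)
  eps <- 1e-12
  with_seed(seed, {
    hits <- sum(vapply(seq_len(n_perm), function(i)
      abs(cor(rx, sample(ry))) >= abs(cc) - eps, NA))
    list(cc = cc, p_value = (1 + hits) / (1 + n_perm))
  })
}
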