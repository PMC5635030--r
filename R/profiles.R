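# Gene profiles: normalization, prevalence filtering, feature summarization,
# and alignment-hit filtering into best-hit annotation maps.

#' Convert gene counts to relative abundances
#'
#' Each sample column is divided by its column sum; zeros are preserved.
#'
#' @param counts non-negative gene-by-sample matrix with dimnames.
#' @return matrix of per-sample relative abundances (columns sum to 1).
#' @export
relative_abundance <- function(counts) {
  assert_abundance(counts, "count matrix")
  cs <- colSums(counts)
  if (any(cs == 0))
    stop_input("sample(s) with all-zero counts: %s",
               paste(colnames(counts)[cs == 0], collapse = ", "))
  sweep(counts, 2, cs, "/")
}

#' Remove rarely detected features
#'
#' Drops features detected (strictly positive abundance) in fewer than
#' `min_samples` samples, mirroring the removal of catalog genes detected in
#' fewer than 10 of the cohort samples before co-abundance binning. Columns
#' are deliberately not renormalized afterwards, so feature sums stay
#' comparable with the unfiltered profile; set `renormalize = TRUE` for
#' sensitivity analyses.
#'
#' @param m abundance matrix (features x samples).
#' @param min_samples detection threshold (default 10).
#' @param renormalize rescale each column to sum 1 after filtering.
#' @return the filtered matrix (possibly with zero rows).
#' @export
filter_low_occurrence <- function(m, min_samples = 10L, renormalize = FALSE) {
  assert_abundance(m)
  if (min_samples < 1L) stop_input("min_samples must be >= 1")
  keep <- rowSums(m > 0) >= min_samples
  out <- m[keep, , drop = FALSE]
  if (renormalize && nrow(out)) {
    cs <- colSums(out)
    cs[cs == 0] <- 1
    out <- sweep(out, 2, cs, "/")
  }
  out
}

#' Sum gene abundances into annotated features
#'
#' Aggregates gene-level abundances to genus/species/KO/enzyme/virus level:
#' the abundance of a feature in a sample is the sum of the relative
#' abundances of its member genes. Genes without an annotation are dropped
#' (their mass is not redistributed).
#'
#' @param m gene-by-sample abundance matrix.
#' @param ann annotation map: data.frame with `gene_id`, `feature_id` (and
#'   optional `identity`, `score`), or a named character vector gene -> label.
#' @return feature-by-sample matrix, features sorted lexicographically.
#' @export
aggregate_features <- function(m, ann) {
  assert_abundance(m)
  ann <- as_annotation(ann)
  ann <- ann[ann$gene_id %in% rownames(m), , drop = FALSE]
  if (nrow(ann) == 0L)
    return(matrix(0, 0, ncol(m), dimnames = list(character(0), colnames(m))))
  fac <- factor(ann$feature_id, levels = sort(unique(ann$feature_id)))
  sub <- m[ann$gene_id, , drop = FALSE]
  out <- rowsum(sub, fac)
  rownames(out) <- levels(fac)
  out
}

#' Reduce an alignment hit table to best-hit annotations
#'
#' Applies the alignment-screen used for functional annotation: keep, per
#' gene, the highest-scoring hit whose identity, bit score and (optionally)
#' E-value pass strict thresholds, e.g. identity > 35, score > 60 and
#' E < 1e-3 for protein hits, or identity > 65 and score > 60 for nucleotide
#' hits against viral genomes. Score ties break by higher identity, then by
#' lexicographic target id. Malformed rows (missing fields, identity outside
#' [0, 100], negative E-value) are skipped with one summary warning.
#'
#' @param hits data.frame with columns `gene_id`, `target_id`, `identity`
#'   (percent), `score` (bit score) and optional `evalue`.
#' @param min_identity,min_score strict lower thresholds.
#' @param max_evalue strict upper E-value threshold, or `NULL` to skip.
#' @return annotation data.frame (`gene_id`, `feature_id`, `identity`,
#'   `score`), one row per gene that had a passing hit.
#' @export
filter_best_hits <- function(hits, min_identity, min_score, max_evalue = NULL) {
  need <- c("gene_id", "target_id", "identity", "score")
  if (!is.data.frame(hits) || !all(need %in% names(hits)))
    stop_input("hits must have columns gene_id, target_id, identity, score")
  if (!is.finite(min_identity) || !is.finite(min_score))
    stop_input("thresholds must be finite")
  identity <- suppressWarnings(as.numeric(hits$identity))
  score <- suppressWarnings(as.numeric(hits$score))
  evalue <- if ("evalue" %in% names(hits))
    suppressWarnings(as.numeric(hits$evalue)) else rep(NA_real_, nrow(hits))
  bad <- is.na(hits$gene_id) | is.na(hits$target_id) |
    !is.finite(identity) | identity < 0 | identity > 100 |
    !is.finite(score) |
    (if (!is.null(max_evalue)) !is.finite(evalue) | evalue < 0 else
       (!is.na(evalue) & evalue < 0))
  if (any(bad))
    warning(sprintf("filter_best_hits: skipped %d malformed hit row(s)", sum(bad)))
  ok <- !bad & identity > min_identity & score > min_score
  if (!is.null(max_evalue)) ok <- ok & evalue < max_evalue
  h <- data.frame(gene_id = as.character(hits$gene_id)[ok],
                  feature_id = as.character(hits$target_id)[ok],
                  identity = identity[ok], score = score[ok],
                  stringsAsFactors = FALSE)
  if (nrow(h) == 0L) return(h)
  ord <- order(h$gene_id, -h$score, -h$identity, h$feature_id)
  h <- h[ord, , drop = FALSE]
  h <- h[!duplicated(h$gene_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}
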