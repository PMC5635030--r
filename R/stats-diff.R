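# Case-control differential abundance, multiple-testing control, and
# gene-content occurrence tests.

#' Benjamini-Hochberg step-up q-values
#'
#' Validates the inputs and applies the standard step-up false-discovery-rate
#' adjustment (via [stats::p.adjust()]), returned in input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    stop_input("p-values must be numeric in [0, 1]")
  p.adjust(p_values, method = "BH")
}

# two-sided Wilcoxon rank-sum p plus enrichment direction from mean ranks
wilcoxon_two_group <- function(x, g1, g2) {
  a <- x[g1]; b <- x[g2]
  if (length(unique(c(a, b))) == 1L)
    return(list(p = 1, direction = 0L))
  p <- suppressWarnings(wilcox.test(a, b, exact = NULL)$p.value)
  rk <- rank(c(a, b))
  d <- mean(rk[seq_along(a)]) - mean(rk[-seq_along(a)])
  list(p = p, direction = if (d > 0) 1L else if (d < 0) -1L else 0L)
}

#' Differential abundance between two sample groups
#'
#' Two-sided Wilcoxon rank-sum test per feature, Benjamini-Hochberg control
#' across features, and an enrichment direction taken from which group holds
#' the larger mean rank (features constant across all samples get p = 1 and
#' direction "none").
#'
#' @param m feature-by-sample abundance matrix.
#' @param groups two-level factor over samples; the **first** level is
#'   treated as the case group.
#' @param q_cut significance threshold echoed in the `significant` column
#'   (default 0.05).
#' @return data.frame: `feature_id`, `median_case`, `median_control`,
#'   `direction` (case-enriched / control-enriched / none), `p_value`,
#'   `q_value`, `significant`.
#' @export
differential_abundance <- function(m, groups, q_cut = 0.05) {
  assert_abundance(m)
  groups <- assert_two_groups(groups, ncol(m))
  lv <- levels(groups)
  i1 <- which(groups == lv[1]); i2 <- which(groups == lv[2])
  if (length(i1) < 2L || length(i2) < 2L)
    stop_input("each group needs at least 2 samples")
  res <- lapply(seq_len(nrow(m)), function(i)
    wilcoxon_two_group(m[i, ], i1, i2))
  p <- vapply(res, `[[`, 0, "p")
  dir <- vapply(res, `[[`, 0L, "direction")
  q <- benjamini_hochberg(p)
  data.frame(feature_id = rownames(m),
             median_case = apply(m[, i1, drop = FALSE], 1, median),
             median_control = apply(m[, i2, drop = FALSE], 1, median),
             direction = c("control-enriched", "none", "case-enriched")[dir + 2L],
             p_value = p, q_value = q,
             significant = q < q_cut,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher exact tests on gene presence/absence
#'
#' For each gene, a two-sided Fisher exact test on its 2x2 occurrence table
#' (present/absent x case/control), with Benjamini-Hochberg q-values across
#' genes. This is the occurrence screen applied to per-species gene
#' presence/absence matrices.
#'
#' @param presence logical (or 0/1) gene-by-sample matrix.
#' @param groups two-level factor over samples.
#' @return data.frame: `gene_id`, `n_present_case`, `n_present_control`,
#'   `p_value`, `q_value`.
#' @export
fisher_gene_content <- function(presence, groups) {
  if (!is.matrix(presence)) stop_input("presence must be a matrix")
  if (is.numeric(presence)) {
    if (!all(presence %in% c(0, 1)))
      stop_input("presence entries must be logical or 0/1")
    presence <- presence > 0
  }
  if (!is.logical(presence)) stop_input("presence entries must be logical or 0/1")
  groups <- assert_two_groups(groups, ncol(presence))
  lv <- levels(groups)
  g1 <- groups == lv[1]
  p <- vapply(seq_len(nrow(presence)), function(i) {
    x <- presence[i, ]
    tab <- matrix(c(sum(x & g1), sum(!x & g1),
                    sum(x & !g1), sum(!x & !g1)), 2)
    fisher.test(tab)$p.value
  }, 0)
  data.frame(gene_id = rownames(presence),
             n_present_case = rowSums(presence[, g1, drop = FALSE]),
             n_present_control = rowSums(presence[, !g1, drop = FALSE]),
             p_value = p, q_value = benjamini_hochberg(p),
             row.names = NULL, stringsAsFactors = FALSE)
}
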