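# Reporter-score enrichment of KO modules.
#
# Each KO occurring in enough samples gets a signed Z-score from a one-tail
# Wilcoxon rank-sum test between cases and controls; a module aggregates its
# member KOs' Z-scores as sum(Z)/sqrt(k) and is corrected against the mean
# and sd of the same aggregate over random same-size KO sets. |score| >= 1.6
# is the one-tail 95% detection threshold; 1.96 the two-sided band drawn on
# plots.

#' Normal-quantile thresholds used for reporter scores
#'
#' @return named vector: `one_sided_95` (the detection threshold, ~1.6 at
#'   one decimal) and `two_sided_95` (~1.96).
#' @export
reporter_score_thresholds <- function() {
  c(one_sided_95 = qnorm(0.95), two_sided_95 = qnorm(0.975))
}

# signed Z per KO: smaller of the two one-sided Wilcoxon p-values, sign
# positive when the case group holds the larger mean rank
ko_z_scores <- function(ko_matrix, case_idx, ctrl_idx, adjust = FALSE,
                        z_clamp = 8) {
  p_dir <- t(vapply(seq_len(nrow(ko_matrix)), function(i) {
    x <- ko_matrix[i, case_idx]; y <- ko_matrix[i, ctrl_idx]
    if (length(unique(c(x, y))) == 1L) return(c(0.5, 0))
    pg <- suppressWarnings(wilcox.test(x, y, alternative = "greater")$p.value)
    pl <- suppressWarnings(wilcox.test(x, y, alternative = "less")$p.value)
    if (pg <= pl) c(pg, 1) else c(pl, -1)
  }, c(0, 0)))
  p <- p_dir[, 1]
  if (adjust) p <- benjamini_hochberg(p)
  z <- qnorm(1 - p) * p_dir[, 2]
  z <- pmax(pmin(z, z_clamp), -z_clamp)
  names(z) <- rownames(ko_matrix)
  z
}

#' Reporter scores for KO modules
#'
#' @param ko_matrix KO-by-sample abundance matrix.
#' @param groups two-level factor over samples; first level = case.
#' @param module_map named list: module id -> character vector of member
#'   KOs. KOs absent from the matrix (or filtered out) are dropped with a
#'   warning; modules with no remaining KOs are excluded.
#' @param min_samples KOs must occur (abundance > 0) in strictly more than
#'   this many samples to be scored (default 5).
#' @param n_background number of random same-size KO sets used to center and
#'   scale each module's raw aggregate (default 1000).
#' @param seed integer seed for the background draws.
#' @param adjust_p compute Z-scores from Benjamini-Hochberg-adjusted one-tail
#'   p-values instead of raw ones.
#' @param z_clamp clamp |Z| of individual KOs (numerical guard, default 8).
#' @param score_threshold detection threshold on |corrected score| used to
#'   set the `direction` field (default the one-tail 95% quantile, ~1.645).
#' @return data.frame: `module_id`, `reporter_score` (corrected, signed
#'   z-units), `n_kos`, `direction` (case / control / none).
#' @export
reporter_scores <- function(ko_matrix, groups, module_map,
                            min_samples = 5L, n_background = 1000L,
                            seed = 1L, adjust_p = FALSE, z_clamp = 8,
                            score_threshold = qnorm(0.95)) {
  assert_abundance(ko_matrix)
  groups <- assert_two_groups(groups, ncol(ko_matrix))
  if (length(module_map) == 0L)
    stop_input("module_map is empty")
  lv <- levels(groups)
  case_idx <- which(groups == lv[1]); ctrl_idx <- which(groups == lv[2])

  occ <- rowSums(ko_matrix > 0)
  scored <- ko_matrix[occ > min_samples, , drop = FALSE]
  if (nrow(scored) < 2L)
    stop_input("fewer than 2 KOs pass the occurrence filter")
  z <- ko_z_scores(scored, case_idx, ctrl_idx, adjust = adjust_p,
                   z_clamp = z_clamp)

  all_requested <- unique(unlist(module_map, use.names = FALSE))
  missing <- setdiff(all_requested, names(z))
  if (length(missing))
    warning(sprintf("reporter_scores: %d KO(s) absent after filtering",
                    length(missing)))

  sizes <- vapply(module_map, function(k) length(intersect(k, names(z))), 0L)
  keep <- sizes >= 1L
  module_map <- module_map[keep]
  sizes <- sizes[keep]
  if (length(module_map) == 0L)
    return(data.frame(module_id = character(0), reporter_score = numeric(0),
                      n_kos = integer(0), direction = character(0)))

  with_seed(seed, {
    # background aggregates per distinct module size
    bg <- lapply(sort(unique(sizes)), function(k) {
      draws <- vapply(seq_len(n_background), function(i)
        sum(z[sample.int(length(z), k)]) / sqrt(k), 0)
      c(mean = mean(draws), sd = sd(draws))
    })
    names(bg) <- as.character(sort(unique(sizes)))
    score <- vapply(seq_along(module_map), function(i) {
      kos <- intersect(module_map[[i]], names(z))
      k <- length(kos)
      raw <- sum(z[kos]) / sqrt(k)
      b <- bg[[as.character(k)]]
      (raw - b["mean"]) / b["sd"]
    }, 0)
    data.frame(module_id = names(module_map),
               reporter_score = score,
               n_kos = sizes,
               direction = ifelse(abs(score) < score_threshold, "none",
                                  ifelse(score > 0, "case", "control")),
               row.names = NULL, stringsAsFactors = FALSE)
  })
}
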