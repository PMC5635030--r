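# Clinical-index association screening and medication-confounder analysis.

#' Associate MLGs with clinical indices
#'
#' Mirrors the two-stage screen used for microbiome/clinical-index links:
#' per index, a cross-validated regression-forest selection ([rfcv_select()]
#' with squared-error loss) pre-selects a small MLG panel, then each
#' selected MLG is tested against the index by permutation-tested Spearman
#' correlation. Pairs are retained when the permutation p-value is below
#' `p_max` and |cc| reaches `cc_min`; associations with |cc| > 0.25 are
#' classed strong.
#'
#' @param mlg_matrix MLG-by-sample abundance matrix.
#' @param indices data.frame of numeric clinical indices, one row per sample
#'   (matrix column order); missing values allowed (pairwise complete).
#' @param n_perm permutations for the Spearman null (default 1000).
#' @param cc_min minimum |Spearman cc| (default 0.2).
#' @param p_max maximum permutation p (default 0.05).
#' @param strong_cc |cc| bound separating strong associations (default 0.25).
#' @param folds,repeats,num_trees forest cross-validation controls.
#' @param seed integer seed.
#' @return data.frame: `index`, `mlg`, `cc`, `p_value`, `strength`
#'   (strong/weak); zero rows if nothing passes.
#' @export
clinical_association <- function(mlg_matrix, indices, n_perm = 1000L,
                                 cc_min = 0.2, p_max = 0.05,
                                 strong_cc = 0.25, folds = 5L, repeats = 2L,
                                 num_trees = 200L, seed = 1L) {
  assert_abundance(mlg_matrix)
  if (!is.data.frame(indices) || nrow(indices) != ncol(mlg_matrix))
    stop_input("indices must be a data.frame with one row per sample")
  out <- list()
  for (idx in names(indices)) {
    yv <- as.numeric(indices[[idx]])
    ok <- !is.na(yv)
    if (sum(ok) < folds * 2L) {
      warning(sprintf("index %s skipped: too few complete samples", idx))
      next
    }
    sub <- mlg_matrix[, ok, drop = FALSE]
    sel <- rfcv_select(sub, yv[ok], folds = folds, repeats = repeats,
                       max_panel = min(25L, nrow(sub)),
                       seed = child_seed(seed, match(idx, names(indices))),
                       num_trees = num_trees)
    for (mlg in sel$chosen_panel) {
      sp <- tryCatch(
        spearman_permutation(sub[mlg, ], yv[ok], n_perm = n_perm,
                             seed = child_seed(seed, 1000 +
                                               match(idx, names(indices)))),
        error = function(e) NULL)
      if (is.null(sp)) next
      if (sp$p_value < p_max && abs(sp$cc) >= cc_min)
        out[[length(out) + 1L]] <-
          data.frame(index = idx, mlg = mlg, cc = sp$cc,
                     p_value = sp$p_value,
                     strength = if (abs(sp$cc) > strong_cc) "strong" else "weak",
                     stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(index = character(0), mlg = character(0),
                      cc = numeric(0), p_value = numeric(0),
                      strength = character(0)))
  do.call(rbind, out)
}

#' Medication-stratified classifier and community-shift comparison
#'
#' For each drug, three two-way cross-validated random-forest classifiers
#' are evaluated — treated cases vs controls, untreated cases vs controls,
#' and treated vs untreated cases — each summarized by out-of-fold AUC and
#' Youden's index. A disease signal dominating the drug signal shows up as
#' both case-vs-control AUCs exceeding the treated-vs-untreated AUC. A
#' Jensen-Shannon PERMANOVA among cases additionally tests whether the drug
#' shifts the community at all.
#'
#' @param m feature-by-sample abundance matrix.
#' @param labels two-level case/control factor (first level = case).
#' @param drug_flags data.frame/matrix of logicals, one column per drug, one
#'   row per sample; flags are meaningful for cases (controls untreated).
#' @param folds,repeats,num_trees forest cross-validation controls.
#' @param n_perm PERMANOVA permutations (default 999).
#' @param min_stratum smallest stratum size for which a comparison is
#'   computed (default `max(folds, 8)`); smaller ones are reported as `NA`.
#' @param seed integer seed.
#' @return list with `classifiers` (data.frame: drug, comparison, n_a, n_b,
#'   auc, youden) and `permanova` (data.frame: drug, pseudo_F, r_squared,
#'   p_value).
#' @export
medication_analysis <- function(m, labels, drug_flags, folds = 5L,
                                repeats = 5L, num_trees = 500L,
                                n_perm = 999L, min_stratum = NULL,
                                seed = 1L) {
  assert_abundance(m)
  labels <- assert_two_groups(labels, ncol(m))
  min_stratum <- min_stratum %||% max(folds, 8L)
  lv <- levels(labels)
  is_case <- labels == lv[1]
  drug_flags <- as.data.frame(drug_flags)
  if (nrow(drug_flags) != ncol(m))
    stop_input("drug_flags must have one row per sample")

  two_way <- function(ix_a, ix_b, lab_a, lab_b, sd) {
    if (length(ix_a) < min_stratum || length(ix_b) < min_stratum)
      return(c(NA_real_, NA_real_))
    ix <- c(ix_a, ix_b)
    y <- factor(rep(c(lab_a, lab_b), c(length(ix_a), length(ix_b))),
                levels = c(lab_a, lab_b))
    pr <- cv_forest_probs(m[, ix, drop = FALSE], y, folds = folds,
                          repeats = repeats, seed = sd,
                          num_trees = num_trees)
    rr <- roc_analysis(pr, y)
    c(rr$auc, rr$youden_index)
  }

  cls <- list(); pmv <- list()
  for (d in names(drug_flags)) {
    fl <- as.logical(drug_flags[[d]])
    i_cd <- which(is_case & fl)       # cases on the drug
    i_cn <- which(is_case & !fl)      # cases off the drug
    i_ct <- which(!is_case)           # controls
    sd0 <- child_seed(seed, match(d, names(drug_flags)) * 17)
    combos <- list(
      list("case_drug_vs_control", i_cd, i_ct, "drug", "control"),
      list("case_nodrug_vs_control", i_cn, i_ct, "nodrug", "control"),
      list("case_drug_vs_case_nodrug", i_cd, i_cn, "drug", "nodrug"))
    for (k in seq_along(combos)) {
      cb <- combos[[k]]
      av <- two_way(cb[[2]], cb[[3]], cb[[4]], cb[[5]],
                    child_seed(sd0, k))
      cls[[length(cls) + 1L]] <-
        data.frame(drug = d, comparison = cb[[1]],
                   n_a = length(cb[[2]]), n_b = length(cb[[3]]),
                   auc = av[1], youden = av[2], stringsAsFactors = FALSE)
    }
    # community shift among cases
    if (length(i_cd) >= 2L && length(i_cn) >= 2L) {
      dmat <- distance_matrix(m[, c(i_cd, i_cn), drop = FALSE],
                              "jensen_shannon")
      pv <- permanova(dmat,
                      rep(c("drug", "nodrug"),
                          c(length(i_cd), length(i_cn))),
                      n_perm = n_perm, seed = child_seed(sd0, 9),
                      factor_id = d)
      pmv[[length(pmv) + 1L]] <-
        data.frame(drug = d, pseudo_F = pv$pseudo_F,
                   r_squared = pv$r_squared, p_value = pv$p_value,
                   stringsAsFactors = FALSE)
    }
  }
  list(classifiers = do.call(rbind, cls),
       permanova = if (length(pmv)) do.call(rbind, pmv) else
         data.frame(drug = character(0), pseudo_F = numeric(0),
                    r_squared = numeric(0), p_value = numeric(0)))
}
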