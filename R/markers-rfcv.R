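# Cross-validated random-forest marker selection (RFCV) and ROC evaluation.
#
# Within each training fold, features are ranked by forest importance and
# nested top-k panels are scored on the held-out fold; the error curves from
# all folds x repeats are averaged, and the minimum of the averaged curve
# plus the standard deviation at that point is the cutoff. All panel sizes
# (<= max_panel) with error below the cutoff are candidates and the smallest
# is chosen.

stratified_folds <- function(labels, folds, seed) {
  assign <- integer(length(labels))
  with_seed(seed, {
    for (lv in levels(labels)) {
      ix <- which(labels == lv)
      assign[ix] <- sample(rep(seq_len(folds), length.out = length(ix)))
    }
  })
  assign
}

fit_ranger <- function(X, y, num_trees, seed, importance = "none",
                       probability = FALSE) {
  ranger::ranger(x = X, y = y, num.trees = num_trees, seed = seed,
                 num.threads = 1L, importance = importance,
                 probability = probability, verbose = FALSE)
}

# predict with an explicit seed: ranger otherwise draws its vote-tie-break
# seed from the global RNG, breaking run-to-run reproducibility
predict_ranger <- function(rf, X, seed) {
  stats::predict(rf, X, num.threads = 1L, seed = seed)$predictions
}

downsample_index <- function(labels, idx, seed) {
  tab <- table(labels[idx])
  nmin <- min(tab)
  with_seed(seed, {
    unlist(lapply(names(tab), function(lv) {
      ix <- idx[labels[idx] == lv]
      if (length(ix) > nmin) sample(ix, nmin) else ix
    }), use.names = FALSE)
  })
}

panel_size_grid <- function(p, max_panel) {
  sizes <- seq_len(min(p, max_panel))
  if (p > max_panel) {
    extra <- unique(round(max_panel * 1.6^(1:20)))
    sizes <- c(sizes, extra[extra < p], p)
  }
  unique(sizes)
}

#' Cross-validated random-forest marker selection
#'
#' Repeated stratified k-fold cross-validation of a random-forest model with
#' nested feature elimination: per training fold, features are ranked by
#' impurity importance and top-k panels evaluated on the held-out fold. The
#' averaged error curve's minimum plus its standard deviation gives the
#' cutoff; all panel sizes up to `max_panel` with error under the cutoff are
#' candidates, and the smallest becomes the marker panel. Panel membership
#' is the top of the full-data importance ranking; out-of-fold disease
#' probabilities are computed at the chosen panel size with each training
#' fold's own feature ranking, so neither model fitting nor feature
#' selection ever sees the held-out samples.
#'
#' @param m feature-by-sample abundance matrix.
#' @param labels factor over samples; two-level for the case/control
#'   classifier (first level = case) or multi-level (see `balance`). A
#'   numeric vector switches to regression forests with squared-error loss.
#' @param folds,repeats cross-validation geometry (default fivefold, five
#'   repeats).
#' @param max_panel largest candidate panel (default 25).
#' @param balance downsample every training class to the smallest class
#'   size, for unequal multi-class designs.
#' @param seed integer seed; the whole procedure is reproducible given it.
#' @param num_trees trees per forest (default 500).
#' @return list of class `marker_selection`: `ranked_features`,
#'   `panel_sizes`, `error_curve`, `error_sd_at_min`, `cutoff`,
#'   `candidate_panels`, `chosen_panel`, `probabilities` (per sample;
#'   two-level classification only), `task`.
#' @export
rfcv_select <- function(m, labels, folds = 5L, repeats = 5L, max_panel = 25L,
                        balance = FALSE, seed = 1L, num_trees = 500L) {
  assert_abundance(m)
  task <- if (is.numeric(labels)) "regression" else "classification"
  if (task == "classification") {
    labels <- droplevels(as.factor(labels))
    if (nlevels(labels) < 2L) stop_input("labels need >= 2 levels")
    if (any(table(labels) < folds))
      stop_input("a class has fewer members than folds; use fewer folds")
  } else if (length(labels) != ncol(m)) {
    stop_input("labels do not match the number of samples")
  }
  X <- t(m)
  p <- ncol(X)
  sizes <- panel_size_grid(p, max_panel)
  err <- matrix(NA_real_, folds * repeats, length(sizes))
  fold_rankings <- vector("list", folds * repeats)

  row_i <- 0L
  for (r in seq_len(repeats)) {
    fa <- if (task == "classification")
      stratified_folds(labels, folds, child_seed(seed, 100 + r))
    else with_seed(child_seed(seed, 100 + r),
                   sample(rep(seq_len(folds), length.out = nrow(X))))
    for (f in seq_len(folds)) {
      row_i <- row_i + 1L
      tr <- which(fa != f); te <- which(fa == f)
      if (balance && task == "classification")
        tr <- downsample_index(labels, tr, child_seed(seed, 200 + row_i))
      rf <- fit_ranger(X[tr, , drop = FALSE], labels[tr], num_trees,
                       child_seed(seed, 300 + row_i), importance = "impurity")
      imp <- rf$variable.importance
      ranking <- names(imp)[order(-imp, names(imp))]
      fold_rankings[[row_i]] <- ranking
      for (si in seq_along(sizes)) {
        feats <- ranking[seq_len(sizes[si])]
        rf2 <- fit_ranger(X[tr, feats, drop = FALSE], labels[tr], num_trees,
                          child_seed(seed, 400 + row_i * 101 + si))
        pred <- predict_ranger(rf2, X[te, feats, drop = FALSE],
                               child_seed(seed, 800 + row_i * 101 + si))
        err[row_i, si] <- if (task == "classification")
          mean(pred != labels[te]) else mean((pred - labels[te])^2)
      }
    }
  }

  curve <- colMeans(err)
  i_min <- which.min(curve)
  sd_min <- sd(err[, i_min])
  cutoff <- curve[i_min] + sd_min
  cand <- sizes[sizes <= max_panel & curve < cutoff]
  if (length(cand) == 0L && sd_min == 0) {
    # degenerate flat optimum: no error is strictly below min + 0
    cand <- sizes[sizes <= max_panel & curve <= cutoff + 1e-15]
  }
  if (length(cand) == 0L) {
    warning("no panel size under the cutoff within max_panel; using argmin")
    small <- which(sizes <= max_panel)
    cand <- sizes[small[which.min(curve[small])]]
  }
  chosen_size <- min(cand)

  rf_full <- fit_ranger(X, labels, num_trees, child_seed(seed, 7),
                        importance = "impurity")
  imp <- rf_full$variable.importance
  ranked <- names(imp)[order(-imp, names(imp))]
  chosen <- ranked[seq_len(chosen_size)]

  # out-of-fold probabilities at the chosen panel size, on fold splits
  # distinct from those that shaped the error curve; each fold's model uses
  # its own training-fold ranking. Neither feature selection nor model
  # fitting ever sees the held-out samples, and the splits that tuned the
  # panel size are not reused for evaluation.
  probs <- NULL
  if (task == "classification" && nlevels(labels) == 2L) {
    pos <- levels(labels)[1]
    acc <- matrix(0, nrow(X), repeats)
    for (r in seq_len(repeats)) {
      fa <- stratified_folds(labels, folds, child_seed(seed, 1100 + r))
      for (f in seq_len(folds)) {
        tr <- which(fa != f); te <- which(fa == f)
        rf_rank <- fit_ranger(X[tr, , drop = FALSE], labels[tr], num_trees,
                              child_seed(seed, 1200 + r * folds + f),
                              importance = "impurity")
        imp <- rf_rank$variable.importance
        feats <- names(imp)[order(-imp, names(imp))][seq_len(chosen_size)]
        rf <- fit_ranger(X[tr, feats, drop = FALSE], labels[tr], num_trees,
                         child_seed(seed, 500 + r * folds + f),
                         probability = TRUE)
        pr <- predict_ranger(rf, X[te, feats, drop = FALSE],
                             child_seed(seed, 900 + r * folds + f))
        acc[te, r] <- pr[, pos]
      }
    }
    probs <- rowMeans(acc)
    names(probs) <- rownames(X)
  }

  structure(list(ranked_features = ranked,
                 panel_sizes = sizes,
                 error_curve = stats::setNames(curve, sizes),
                 error_sd_at_min = sd_min,
                 cutoff = cutoff,
                 candidate_panels = cand,
                 chosen_panel = chosen,
                 probabilities = probs,
                 task = task),
            class = "marker_selection")
}

#' Out-of-fold cross-validated forest probabilities
#'
#' Repeated stratified k-fold cross-validation of a probability forest on
#' the full feature matrix; each sample's disease probability is predicted
#' only by forests that never saw it, averaged over repeats.
#'
#' @inheritParams rfcv_select
#' @return named numeric vector of probabilities of the first factor level.
#' @export
cv_forest_probs <- function(m, labels, folds = 5L, repeats = 5L, seed = 1L,
                            num_trees = 500L) {
  assert_abundance(m)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop_input("two-level labels required")
  if (any(table(labels) < folds))
    stop_input("a class has fewer members than folds")
  X <- t(m)
  pos <- levels(labels)[1]
  acc <- matrix(0, nrow(X), repeats)
  for (r in seq_len(repeats)) {
    fa <- stratified_folds(labels, folds, child_seed(seed, 100 + r))
    for (f in seq_len(folds)) {
      tr <- which(fa != f); te <- which(fa == f)
      rf <- fit_ranger(X[tr, , drop = FALSE], labels[tr], num_trees,
                       child_seed(seed, 600 + r * folds + f),
                       probability = TRUE)
      acc[te, r] <- predict_ranger(rf, X[te, , drop = FALSE],
                                   child_seed(seed, 700 + r * folds + f))[, pos]
    }
  }
  stats::setNames(rowMeans(acc), rownames(X))
}

#' ROC curve, AUC with confidence interval, and Youden operating point
#'
#' AUC by the rank statistic (ties credited 0.5) with a DeLong 95%
#' confidence interval, both via \pkg{pROC}. The Youden cutoff maximizes
#' sensitivity + specificity - 1; ties resolve to the lowest cutoff.
#'
#' @param probabilities per-sample scores (higher = more case-like).
#' @param labels two-level factor; first level = case.
#' @return list of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `roc_points` (data.frame cutoff/fpr/tpr), `youden_cutoff`,
#'   `youden_index`.
#' @export
roc_analysis <- function(probabilities, labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop_input("both classes must be present")
  if (length(probabilities) != length(labels))
    stop_input("probabilities and labels differ in length")
  lv <- levels(labels)
  r <- pROC::roc(response = labels, predictor = as.numeric(probabilities),
                 levels = c(lv[2], lv[1]), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- tryCatch(suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))),
                 error = function(e) c(NA_real_, auc, NA_real_))
  co <- pROC::coords(r, x = "all", ret = c("threshold", "specificity",
                                           "sensitivity"), transpose = FALSE)
  youden <- co$sensitivity + co$specificity - 1
  jmax <- max(youden)
  j_at <- co$threshold[youden >= jmax - 1e-12]
  list(auc = auc, ci_low = ci[1], ci_high = ci[3],
       roc_points = data.frame(cutoff = co$threshold,
                               fpr = 1 - co$specificity,
                               tpr = co$sensitivity),
       youden_cutoff = min(j_at),
       youden_index = jmax)
}

#' Classifier restricted to TMA-lyase enzyme families
#'
#' Runs the same cross-validated forest marker selection on the
#' trimethylamine-lyase feature matrix (CutC, CutD, YeaW, YeaX) — a
#' deliberately information-poor panel whose AUC bounds how much of the
#' disease signal the TMA pathway alone carries. An all-constant matrix
#' yields degenerate probabilities of 0.5 for every sample.
#'
#' @param enzyme_matrix enzyme-family-by-sample abundance matrix.
#' @inheritParams rfcv_select
#' @return list with `selection` (`marker_selection` or `NULL` when
#'   degenerate) and `roc` (`roc_result`).
#' @export
enzyme_classifier <- function(enzyme_matrix, labels, folds = 5L,
                              repeats = 5L, seed = 1L, num_trees = 500L) {
  assert_abundance(enzyme_matrix)
  labels <- droplevels(as.factor(labels))
  if (all(apply(enzyme_matrix, 1, var) == 0)) {
    probs <- stats::setNames(rep(0.5, ncol(enzyme_matrix)),
                             colnames(enzyme_matrix))
    return(list(selection = NULL, roc = roc_analysis(probs, labels),
                probabilities = probs))
  }
  sel <- rfcv_select(enzyme_matrix, labels, folds = folds, repeats = repeats,
                     max_panel = nrow(enzyme_matrix), seed = seed,
                     num_trees = num_trees)
  list(selection = sel, roc = roc_analysis(sel$probabilities, labels),
       probabilities = sel$probabilities)
}
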