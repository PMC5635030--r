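test_that("ROC analysis matches pairwise-concordance arithmetic", {
  lab <- factor(c("case", "case", "control", "control"),
                levels = c("case", "control"))
  perfect <- roc_analysis(c(0.9, 0.8, 0.4, 0.2), lab)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$youden_index, 1)

  mixed <- roc_analysis(c(0.9, 0.3, 0.5, 0.1), lab)
  expect_equal(mixed$auc, 0.75)          # 3 of 4 concordant pairs

  # swapping class labels mirrors the AUC
  swapped <- roc_analysis(c(0.9, 0.3, 0.5, 0.1),
                          factor(c("control", "control", "case", "case"),
                                 levels = c("case", "control")))
  expect_equal(swapped$auc, 1 - mixed$auc)

  # brute-force concordant pairs on random inputs up to 30 samples
  set.seed(20)
  for (i in 1:5) {
    n <- sample(6:30, 1)
    y <- factor(sample(c("case", "control"), n, replace = TRUE,
                       prob = c(0.5, 0.5)), levels = c("case", "control"))
    if (nlevels(droplevels(y)) < 2) next
    pr <- round(runif(n), 2)             # rounding forces some ties
    expect_equal(roc_analysis(pr, y)$auc, auc_brute_force(pr, y, "case"))
  }
  expect_error(roc_analysis(runif(4), factor(rep("case", 4))), "class")
})

test_that("RFCV is seed-reproducible, caps panels at max_panel, and selects planted markers", {
  set.seed(21)
  n <- 80; p <- 60
  m <- matrix(abs(rnorm(n * p)), p, n,
              dimnames = list(sprintf("f%03d", 1:p), sprintf("s%03d", 1:n)))
  y <- factor(rep(c("case", "control"), each = n / 2),
              levels = c("case", "control"))
  informative <- sprintf("f%03d", 1:3)
  m[informative, y == "case"] <- m[informative, y == "case"] + 2

  sel <- rfcv_select(m, y, folds = 5, repeats = 2, seed = 22, num_trees = 100)
  sel2 <- rfcv_select(m, y, folds = 5, repeats = 2, seed = 22, num_trees = 100)
  expect_identical(sel, sel2)
  expect_true(all(sel$candidate_panels <= 25))
  expect_lte(length(sel$chosen_panel), 25)
  expect_equal(length(sel$chosen_panel), min(sel$candidate_panels))
  expect_gte(length(intersect(sel$chosen_panel, informative)), 2L)
  expect_true(all(sel$probabilities >= 0 & sel$probabilities <= 1))
  expect_equal(sel$cutoff, min(sel$error_curve) + sel$error_sd_at_min)
  expect_gt(roc_analysis(sel$probabilities, y)$auc, 0.9)

  expect_error(rfcv_select(m, factor(c(rep("a", 2), rep("b", n - 2))),
                           folds = 5), "folds")
})

test_that("out-of-fold probabilities never come from a model trained on the sample", {
  set.seed(23)
  n <- 40; p <- 12
  m <- matrix(abs(rnorm(n * p)), p, n,
              dimnames = list(sprintf("f%02d", 1:p), sprintf("s%02d", 1:n)))
  y <- factor(rep(c("case", "control"), each = n / 2),
              levels = c("case", "control"))
  base <- cv_forest_probs(m, y, folds = 4, repeats = 1, seed = 24,
                          num_trees = 100)
  fa <- mlgmwas:::stratified_folds(y, 4, mlgmwas:::child_seed(24, 101))
  target <- which(fa == 1)[1]
  mate <- which(fa == 1)[2]              # same held-out fold as target
  m2 <- m
  m2[, target] <- rev(m2[, target])      # perturb one held-out sample
  pert <- cv_forest_probs(m2, y, folds = 4, repeats = 1, seed = 24,
                          num_trees = 100)
  # its fold-mate's prediction comes from the same unchanged model
  expect_equal(pert[mate], base[mate])
  expect_false(isTRUE(all.equal(pert[target], base[target])))
})

test_that("degenerate and planted enzyme panels behave as expected", {
  zeros <- matrix(0, 4, 30, dimnames = list(c("CutC", "CutD", "YeaW", "YeaX"),
                                            sprintf("s%02d", 1:30)))
  y <- factor(rep(c("case", "control"), each = 15),
              levels = c("case", "control"))
  degen <- enzyme_classifier(zeros, y)
  expect_true(all(degen$probabilities == 0.5))
  expect_equal(degen$roc$auc, 0.5)

  # planted enzyme enrichment: informative but weaker than the full panel
  set.seed(25)
  n <- 80
  enz <- matrix(abs(rnorm(4 * n, 1)), 4, n,
                dimnames = list(c("CutC", "CutD", "YeaW", "YeaX"),
                                sprintf("s%03d", 1:n)))
  yy <- factor(rep(c("case", "control"), each = n / 2),
               levels = c("case", "control"))
  enz[c("YeaW", "YeaX"), yy == "case"] <-
    enz[c("YeaW", "YeaX"), yy == "case"] + 1
  full <- rbind(enz, matrix(abs(rnorm(20 * n)), 20, n,
                            dimnames = list(sprintf("x%02d", 1:20),
                                            sprintf("s%03d", 1:n))))
  full[c("x01", "x02", "x03"), yy == "case"] <-
    full[c("x01", "x02", "x03"), yy == "case"] + 2
  ez <- enzyme_classifier(enz, yy, folds = 5, repeats = 2, seed = 26,
                          num_trees = 100)
  fl <- rfcv_select(full, yy, folds = 5, repeats = 2, seed = 26,
                    num_trees = 100)
  auc_full <- roc_analysis(fl$probabilities, yy)$auc
  expect_gt(ez$roc$auc, 0.6)
  expect_lt(ez$roc$auc, auc_full)
})
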