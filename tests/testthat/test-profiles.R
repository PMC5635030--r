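test_that("relative abundance normalizes columns and flags empty samples", {
  m <- matrix(c(2, 3, 5, 7, 0, 0), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  r <- relative_abundance(m)
  expect_equal(r[, "s1"], c(g1 = 0.2, g2 = 0.3, g3 = 0.5))
  expect_equal(unname(r["g1", "s2"]), 1)

  single <- matrix(7, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(unname(relative_abundance(single)), matrix(1), ignore_attr = TRUE)

  bad <- matrix(c(1, 0, 0, 0), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(relative_abundance(bad), "s2")

  set.seed(1)
  rnd <- matrix(rpois(500, 4), 50, 10,
                dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:10)))
  rnd[1, ] <- rnd[1, ] + 1  # guard against all-zero column
  expect_true(all(abs(colSums(relative_abundance(rnd)) - 1) < 1e-12))
})

test_that("prevalence filter keeps >= min_samples detections and is idempotent", {
  set.seed(2)
  m <- matrix(0, 30, 40, dimnames = list(sprintf("g%02d", 1:30),
                                         sprintf("s%02d", 1:40)))
  occ <- sample(0:40, 30, replace = TRUE)
  for (i in 1:30) if (occ[i] > 0) m[i, sample(40, occ[i])] <- runif(occ[i])
  f <- filter_low_occurrence(m, 10)
  expect_setequal(rownames(f), rownames(m)[rowSums(m > 0) >= 10])
  # boundary: exactly 9 removed, exactly 10 kept
  m2 <- matrix(0, 2, 40, dimnames = list(c("nine", "ten"), colnames(m)))
  m2["nine", 1:9] <- 1; m2["ten", 1:10] <- 1
  expect_equal(rownames(filter_low_occurrence(m2, 10)), "ten")
  # idempotence; no-op at min_samples = 1 when every gene occurs
  expect_identical(filter_low_occurrence(f, 10), f)
  expect_identical(filter_low_occurrence(f, 1), f)
  # columns are not renormalized by default
  expect_true(all(colSums(f) <= colSums(m) + 1e-12))
})

test_that("feature aggregation sums member genes and conserves mass", {
  m <- matrix(c(0.1, 0.2, 0.7, 0.3, 0.3, 0.4), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  ag <- aggregate_features(m, c(g1 = "GenusA", g2 = "GenusA", g3 = "GenusB"))
  expect_equal(unname(ag["GenusA", "s1"]), 0.3)
  empty <- data.frame(gene_id = character(0), feature_id = character(0))
  expect_equal(nrow(aggregate_features(m, empty)), 0L)

  set.seed(3)
  big <- matrix(runif(1000), 100, 10,
                dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:10)))
  partial <- stats::setNames(sample(letters[1:5], 60, replace = TRUE),
                             sample(rownames(big), 60))
  agg <- aggregate_features(big, partial)
  expect_true(all(colSums(agg) <= colSums(big) + 1e-12))
  total <- stats::setNames(sample(letters[1:5], 100, replace = TRUE),
                           rownames(big))
  expect_equal(colSums(aggregate_features(big, total)), colSums(big))
  # linearity
  expect_equal(aggregate_features(big * 3, total),
               3 * aggregate_features(big, total))
})

test_that("best-hit filtering applies strict thresholds and score ordering", {
  hits <- data.frame(
    gene_id = c("g1", "g2", "g3", "g3", "g4", "g5"),
    target_id = c("T1", "T2", "T3", "T4", "T5", "T6"),
    identity = c(36, 34, 50, 50, 35, 80),
    score = c(61, 100, 80, 70, 90, 60),
    evalue = c(1e-4, 1e-9, 1e-5, 1e-5, 1e-5, 1e-5))
  ann <- filter_best_hits(hits, 35, 60, 1e-3)
  expect_equal(ann$feature_id[ann$gene_id == "g1"], "T1")   # passes all
  expect_false("g2" %in% ann$gene_id)                       # identity 34 <= 35
  expect_false("g4" %in% ann$gene_id)                       # identity 35 not > 35
  expect_false("g5" %in% ann$gene_id)                       # score 60 not > 60
  expect_equal(ann$feature_id[ann$gene_id == "g3"], "T3")   # max score wins
  # output targets always come from the gene's own hit rows
  expect_true(all(mapply(function(g, t)
    any(hits$gene_id == g & hits$target_id == t), ann$gene_id, ann$feature_id)))

  # ties on score -> higher identity, then lexicographic target
  ties <- data.frame(gene_id = "g", target_id = c("B", "A", "C"),
                     identity = c(70, 70, 60), score = c(90, 90, 90))
  expect_equal(filter_best_hits(ties, 35, 60)$feature_id, "A")

  # malformed rows skipped with a warning
  mal <- rbind(hits, data.frame(gene_id = "g9", target_id = "T9",
                                identity = 150, score = 99, evalue = 1e-9))
  expect_warning(out <- filter_best_hits(mal, 35, 60, 1e-3), "malformed")
  expect_false("g9" %in% out$gene_id)
})
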