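test_that("normal-quantile detection thresholds round to the printed values", {
  th <- reporter_score_thresholds()
  expect_equal(round(th[["two_sided_95"]], 2), 1.96)
  expect_equal(round(th[["one_sided_95"]], 1), 1.6)
})

test_that("single-KO modules reduce to the standardized KO Z-score", {
  set.seed(13)
  n_ko <- 40
  m <- matrix(abs(rnorm(n_ko * 30)) + 0.01, n_ko, 30,
              dimnames = list(sprintf("K%05d", 1:n_ko), sprintf("s%02d", 1:30)))
  g <- rep(c("case", "control"), each = 15)
  mods <- stats::setNames(as.list(rownames(m)[1:10]), sprintf("M%02d", 1:10))
  rs <- reporter_scores(m, g, mods, min_samples = 3, n_background = 4000,
                        seed = 14)
  z <- mlgmwas:::ko_z_scores(m, which(g == "case"), which(g == "control"))
  standardized <- (z[1:10] - mean(z)) / sd(z)
  expect_lt(max(abs(rs$reporter_score - unname(standardized))), 0.15)
  expect_true(all(rs$n_kos == 1L))
})

test_that("a planted all-enriched module clears the 1.96 band", {
  catg <- planted_ko_catalog(n_genomes = 20, genes_each = 30, seed = 15)
  lfc <- stats::setNames(rep(0, 20), catg$genome_ids)
  lfc["G001"] <- 1.5
  model <- community_model(catg, case_log2_fold_change = lfc,
                           sequencing_depth = 1e5)
  coh <- simulate_cohort(catg, model, 50, 50, seed = 16)
  ko_prof <- aggregate_features(relative_abundance(coh$counts),
                                catg$gene_to_ko)
  mods <- list(planted = catg$ko_of_genome[["G001"]],
               null_a = catg$ko_of_genome[["G005"]],
               null_b = catg$ko_of_genome[["G006"]])
  rs <- reporter_scores(ko_prof, cohort_groups(coh), mods,
                        n_background = 1000, seed = 17)
  planted <- rs[rs$module_id == "planted", ]
  expect_gt(planted$reporter_score, 1.96)
  expect_equal(planted$direction, "case")
  # module truth direction from the generator agrees
  catg$module_map <- mods
  dir <- mlgmwas:::module_truth_direction(catg, lfc)
  expect_equal(dir[["planted"]], 1L)
  expect_equal(dir[["null_a"]], 0L)
})

test_that("missing KOs are dropped with a warning and empty modules excluded", {
  set.seed(18)
  m <- matrix(abs(rnorm(200)) + 0.01, 10, 20,
              dimnames = list(sprintf("K%05d", 1:10), sprintf("s%02d", 1:20)))
  g <- rep(c("case", "control"), each = 10)
  mods <- list(ok = rownames(m)[1:3],
               partial = c(rownames(m)[4], "K99999"),
               gone = c("K88888"))
  expect_warning(rs <- reporter_scores(m, g, mods, min_samples = 3,
                                       n_background = 200, seed = 19),
                 "absent")
  expect_setequal(rs$module_id, c("ok", "partial"))
  expect_equal(rs$n_kos[rs$module_id == "partial"], 1L)
})
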