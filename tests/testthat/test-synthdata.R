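test_that("catalog construction partitions genes and honors annotation rates", {
  catg <- generate_catalog(2, c(3, 3), seed = 1)
  expect_length(catg$gene_ids, 6L)
  expect_equal(unname(table(catg$gene_to_genome)), c(3L, 3L),
               ignore_attr = TRUE)
  expect_setequal(names(catg$gene_to_genome), catg$gene_ids)

  zero_ko <- generate_catalog(3, c(5, 10),
                              annotation_rates = list(ko = 0, enzyme = 0.5,
                                                      virus = 0),
                              seed = 2)
  expect_length(zero_ko$gene_to_ko, 0L)
  expect_gt(length(zero_ko$gene_to_enzyme), 0L)

  big <- generate_catalog(50, c(100, 300), seed = 7)
  again <- generate_catalog(50, c(100, 300), seed = 7)
  expect_identical(big, again)
  expect_equal(length(big$gene_ids), sum(big$genes_per_genome))
  # every module's KOs come from assigned KOs
  expect_true(all(unlist(big$module_map) %in% big$gene_to_ko))

  expect_error(generate_catalog(1), "n_genomes")
  expect_error(generate_catalog(3, c(0, 5)), "genes_per_genome_range")
})

test_that("cohort dimensions, depth conservation and determinism hold", {
  catg <- generate_catalog(5, c(8, 12), seed = 3)
  model <- community_model(catg, sequencing_depth = 2000)
  coh <- simulate_cohort(catg, model, 218, 187, seed = 4)
  expect_equal(nrow(coh$metadata), 405L)
  expect_equal(sum(coh$metadata$group == "case"), 218L)
  expect_equal(sum(coh$metadata$group == "control"), 187L)
  # with no dropout every column sum equals the configured depth exactly
  expect_true(all(colSums(coh$counts) == 2000))
  coh2 <- simulate_cohort(catg, model, 218, 187, seed = 4)
  expect_identical(coh, coh2)

  expect_error(community_model(catg, case_log2_fold_change = c(BAD = 1)),
               "unknown genome")
  expect_error(community_model(catg, dispersion = 0), "dispersion")
})

test_that("null model is symmetric and planted fold change is recovered", {
  catg <- generate_catalog(6, c(5, 5), seed = 5)
  null_model <- community_model(catg, sequencing_depth = 1e4)
  coh <- simulate_cohort(catg, null_model, 100, 100, seed = 6)
  prof <- genome_profile(coh, catg)
  grp <- cohort_groups(coh)
  ratio <- rowMeans(prof[, grp == "case"]) / rowMeans(prof[, grp == "control"])
  expect_true(all(ratio > 0.6 & ratio < 1.7))
  expect_length(coh$truth$true_enriched, 0L)

  # 2^2 = 4-fold plant on a low-abundance genome (small compositional
  # damping): Monte-Carlo mean ratio over 20 seeds near 4
  catg10 <- generate_catalog(10, c(5, 5), seed = 55)
  lfc <- stats::setNames(c(2, rep(0, 9)), catg10$genome_ids)
  base <- stats::setNames(c(-1.5, rep(0, 9)), catg10$genome_ids)
  model <- community_model(catg10, baseline_log_abundance = base,
                           case_log2_fold_change = lfc,
                           sequencing_depth = 1e5)
  ratios <- vapply(1:20, function(s) {
    coh <- simulate_cohort(catg10, model, 50, 50, seed = 1000 + s)
    prof <- genome_profile(coh, catg10)
    grp <- cohort_groups(coh)
    rowMeans(prof[, grp == "case"])[1] / rowMeans(prof[, grp == "control"])[1]
  }, 0)
  expect_gt(mean(ratios), 3.0)
  expect_lt(mean(ratios), 5.3)
})

test_that("within-genome gene correlation exceeds between-genome correlation", {
  catg <- generate_catalog(8, c(10, 10), seed = 8)
  model <- community_model(catg, sequencing_depth = 2e5)
  coh <- simulate_cohort(catg, model, 60, 60, seed = 9)
  prof <- relative_abundance(coh$counts)
  cc <- cor(apply(prof, 1, rank))
  same <- outer(catg$gene_to_genome, catg$gene_to_genome, "==") & upper.tri(cc)
  diffp <- !outer(catg$gene_to_genome, catg$gene_to_genome, "==") & upper.tri(cc)
  expect_gt(mean(cc[same]), mean(cc[diffp]))
})

test_that("ground truth reflects planted effects", {
  fix <- small_cohort()
  truth <- fix$cohort$truth
  expect_setequal(truth$true_enriched, c("G001", "G002"))
  expect_setequal(truth$true_depleted, c("G003", "G004"))
  expect_length(intersect(truth$true_enriched, truth$true_depleted), 0L)
  expect_equal(truth$true_clinical_pairs$genome, "G001")
  # drug flags only among cases
  md <- fix$cohort$metadata
  expect_false(any(md$drug_eff[md$group == "control"]))
})
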