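test_that("planted proportional gene blocks are recovered exactly", {
  m <- planted_block_matrix(2, 150, 30, seed = 41)
  mlgs <- build_mlgs(m, 0.6, min_genes = 100)
  expect_length(mlgs, 2L)
  recovered <- lapply(mlgs, `[[`, "gene_ids")
  planted <- split(rownames(m), sub("_g.*", "", rownames(m)))
  expect_setequal(recovered[[1]], planted[[1]])
  expect_setequal(recovered[[2]], planted[[2]])
})

test_that("size threshold is strict and degenerate inputs are handled", {
  m <- planted_block_matrix(2, 50, 20, seed = 42)
  expect_length(build_mlgs(m, 0.6, min_genes = 100), 0L)
  expect_length(build_mlgs(m, 0.6, min_genes = 50), 0L)   # strict >
  expect_length(build_mlgs(m, 0.6, min_genes = 49), 2L)

  single <- matrix(runif(5), 1, 5, dimnames = list("g1", sprintf("s%d", 1:5)))
  expect_length(build_mlgs(single, 0.6, min_genes = 0), 0L)
  expect_error(build_mlgs(m, 1.2), "cc_threshold")
  expect_error(build_mlgs(m[, 1:2], 0.6), "3 samples")
})

test_that("binning is stable under gene row permutation", {
  m <- planted_block_matrix(3, 40, 25, seed = 43)
  a <- build_mlgs(m, 0.6, min_genes = 10)
  set.seed(1)
  b <- build_mlgs(m[sample(nrow(m)), ], 0.6, min_genes = 10)
  expect_equal(lapply(a, `[[`, "gene_ids"), lapply(b, `[[`, "gene_ids"))
})

test_that("MLG abundance sums member genes and conserves partitioned mass", {
  m <- planted_block_matrix(2, 30, 15, seed = 44)
  mlgs <- build_mlgs(m, 0.6, min_genes = 10)
  ab <- mlg_abundance(mlgs, m)
  one <- mlgs[[1]]
  expect_equal(ab[one$mlg_id, ], colSums(m[one$gene_ids, ]))
  clustered <- unlist(lapply(mlgs, `[[`, "gene_ids"))
  expect_equal(colSums(ab), colSums(m[clustered, ]))
  expect_true(all(colSums(ab) <= colSums(m) + 1e-9))

  toy <- list(list(mlg_id = "MLGx", gene_ids = c("missing_gene"), size = 1))
  expect_error(mlg_abundance(toy, m), "missing_gene")
})

test_that("taxonomy vote needs a strict majority and reports the top three", {
  mlg <- list(mlg_id = "M", size = 10,
              gene_ids = sprintf("g%02d", 1:10))
  votes <- function(counts) {
    # counts: named integer gene counts per genome, summing <= 10
    genome <- rep(names(counts), counts)
    data.frame(gene_id = sprintf("g%02d", seq_along(genome)),
               feature_id = genome, identity = 95)
  }
  expect_equal(assign_taxonomy(mlg, votes(c(A = 6L, B = 4L)))$assigned_taxon, "A")
  t40 <- assign_taxonomy(mlg, votes(c(A = 4L, B = 3L)))
  expect_true(is.na(t40$assigned_taxon))
  expect_equal(t40$top_genomes$genome[1], "A")
  t50 <- assign_taxonomy(mlg, votes(c(A = 5L, B = 3L, C = 2L)))
  expect_true(is.na(t50$assigned_taxon))      # exactly half: strict > 0.5
  expect_equal(t50$top_genomes$genome, c("A", "B", "C"))
  expect_equal(t50$top_genomes$fraction, c(0.5, 0.3, 0.2))

  none <- assign_taxonomy(mlg, data.frame(gene_id = "zz", feature_id = "A"))
  expect_true(is.na(none$assigned_taxon))
  expect_equal(nrow(none$top_genomes), 0L)
})

test_that("planted cohort bins are recovered with high agreement", {
  fix <- small_cohort()
  prof <- filter_low_occurrence(relative_abundance(fix$cohort$counts), 10)
  mlgs <- build_mlgs(prof, 0.6, min_genes = 10)
  expect_gte(length(mlgs), 8L)
  ari <- binning_ari(mlgs, prof, fix$cohort$truth$true_bins)
  expect_gt(ari, 0.8)
})
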