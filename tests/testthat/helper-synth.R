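# Shared fixtures, built in code.

# small cohort with planted enriched/depleted genomes, cached per test run
small_cohort <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    catg <- generate_catalog(10, c(15, 25), seed = 11)
    lfc <- stats::setNames(rep(0, 10), catg$genome_ids)
    lfc[c("G001", "G002")] <- 1.5
    lfc[c("G003", "G004")] <- -1.5
    model <- community_model(catg, case_log2_fold_change = lfc,
                             sequencing_depth = 5e4,
                             clinical_effect_map = list(
                               index_a = list("G001", 1.5, 0.8),
                               index_null = list("G001", 0, 1)),
                             drug_effect_map = list(
                               drug_eff = list("G006", 1.5),
                               drug_null = list("G007", 0)))
    coh <- simulate_cohort(catg, model, 40, 40, seed = 12)
    cache <<- list(catalog = catg, model = model, cohort = coh, lfc = lfc)
    cache
  }
})

# genome-level abundance via the planted bins (true aggregation)
genome_profile <- function(coh, catg) {
  relab <- relative_abundance(coh$counts)
  aggregate_features(relab, catg$gene_to_genome)
}

cohort_groups <- function(coh) {
  factor(coh$metadata$group, levels = c("case", "control"))
}

# matrix with planted proportional gene blocks (noise-free co-abundance)
planted_block_matrix <- function(n_genomes, genes_each, n_samples, seed) {
  withr::with_seed(seed, {
    lat <- matrix(exp(rnorm(n_genomes * n_samples, 0, 1)),
                  n_genomes, n_samples)
    rows <- lapply(seq_len(n_genomes), function(g) {
      w <- exp(rnorm(genes_each, 0, 0.5))
      outer(w, lat[g, ])
    })
    m <- do.call(rbind, rows)
    rownames(m) <- sprintf("G%02d_g%03d", rep(seq_len(n_genomes), each = genes_each),
                           sequence(rep(genes_each, n_genomes)))
    colnames(m) <- sprintf("s%03d", seq_len(n_samples))
    sweep(m, 2, colSums(m), "/")
  })
}

# exhaustive two-sided Wilcoxon rank-sum p by enumeration over rank splits
wilcoxon_enumeration_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(n, n1)
  w_all <- apply(splits, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  lo <- mean(w_all <= w_obs); hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}

# concordant-pair AUC (ties half credit)
auc_brute_force <- function(probs, labels, positive) {
  pos <- probs[labels == positive]; neg <- probs[labels != positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# ARI of recovered MLGs vs planted bins, unassigned genes as singletons
binning_ari <- function(mlgs, prof, true_bins) {
  memb <- mlg_membership(mlgs)
  lab <- stats::setNames(paste0("single_", seq_len(nrow(prof))), rownames(prof))
  lab[memb$gene_id] <- memb$mlg_id
  mclust::adjustedRandIndex(lab, true_bins[names(lab)])
}

# catalog whose KO map is genome-coherent: each genome carries its own KOs,
# so modules made of one genome's KOs inherit that genome's fold change
planted_ko_catalog <- function(n_genomes = 20, genes_each = 30,
                               kos_per_genome = 5, seed = 31) {
  catg <- generate_catalog(n_genomes, c(genes_each, genes_each),
                           annotation_rates = list(ko = 0, enzyme = 0,
                                                   virus = 0),
                           n_modules = 0, seed = seed)
  gene_to_ko <- character(0)
  ko_of_genome <- list()
  for (i in seq_along(catg$genome_ids)) {
    g <- catg$genome_ids[i]
    kos <- sprintf("K%05d", (i - 1) * kos_per_genome + seq_len(kos_per_genome))
    ko_of_genome[[g]] <- kos
    genes <- names(catg$gene_to_genome)[catg$gene_to_genome == g]
    per <- floor(length(genes) / kos_per_genome)
    for (k in seq_along(kos)) {
      gk <- genes[(k - 1) * per + seq_len(per)]
      gene_to_ko[gk] <- kos[k]
    }
  }
  catg$gene_to_ko <- gene_to_ko
  catg$ko_of_genome <- ko_of_genome
  catg
}
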