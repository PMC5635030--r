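# Synthetic catalogs and cohorts with planted ground truth.
#
# The generator emulates, at toy scale, a reference gene catalog in which each
# microbial genome contributes a block of co-abundant genes, a log-normal
# community composition, case/control fold changes on selected genomes,
# multinomial sequencing-depth count noise, detection dropouts, annotation
# maps (genome, KO, enzyme family, virus) and correlated clinical indices.
# Every stochastic choice flows from one explicit seed so downstream stages
# have a reproducible parameter-recovery surface.

TMA_LYASE_FAMILIES <- c("CutC", "CutD", "YeaW", "YeaX")

#' Generate a synthetic gene catalog
#'
#' Builds a toy gene catalog in which every gene belongs to exactly one
#' genome, and partial annotation maps assign approximately the requested
#' fraction of genes to KEGG Orthology (KO) groups, trimethylamine-lyase
#' enzyme families (CutC/CutD/YeaW/YeaX) and viral genomes. KO modules are
#' drawn from the set of KOs actually assigned, so reporter-score analyses
#' always have resolvable members.
#'
#' @param n_genomes number of genomes (>= 2).
#' @param genes_per_genome_range integer interval `c(lo, hi)`, `lo >= 1`;
#'   each genome's gene count is drawn uniformly from it.
#' @param annotation_rates list with fractions `ko`, `enzyme`, `virus` giving
#'   the expected proportion of genes carrying each annotation.
#' @param n_kos size of the KO label pool.
#' @param n_modules number of KO modules to define.
#' @param module_size_range interval of KOs per module.
#' @param n_viruses size of the virus label pool.
#' @param seed integer seed; the catalog is deterministic given it.
#' @return an object of class `synthetic_catalog`: a list with `genome_ids`,
#'   `gene_ids`, `genes_per_genome`, `gene_to_genome` (named character
#'   vector), `gene_genome_identity` (simulated alignment identity, percent),
#'   partial maps `gene_to_ko`, `gene_to_enzyme`, `gene_to_virus`, and
#'   `module_map` (named list of KO character vectors).
#' @export
generate_catalog <- function(n_genomes,
                             genes_per_genome_range = c(100L, 300L),
                             annotation_rates = list(ko = 0.4, enzyme = 0.02,
                                                     virus = 0.03),
                             n_kos = 150L, n_modules = 20L,
                             module_size_range = c(4L, 8L),
                             n_viruses = 10L, seed = 1L) {
  if (length(n_genomes) != 1L || n_genomes < 2L)
    stop_input("n_genomes must be a single integer >= 2")
  rng <- as.integer(genes_per_genome_range)
  if (length(rng) != 2L || rng[1] < 1L || rng[2] < rng[1])
    stop_input("genes_per_genome_range must be c(lo, hi) with 1 <= lo <= hi")
  rates <- list(ko = annotation_rates$ko %||% 0,
                enzyme = annotation_rates$enzyme %||% 0,
                virus = annotation_rates$virus %||% 0)
  if (any(unlist(rates) < 0 | unlist(rates) > 1))
    stop_input("annotation rates must lie in [0, 1]")

  with_seed(seed, {
    genome_ids <- sprintf("G%03d", seq_len(n_genomes))
    genes_per_genome <- if (rng[1] == rng[2]) rep(rng[1], n_genomes) else
      sample(seq(rng[1], rng[2]), n_genomes, replace = TRUE)
    names(genes_per_genome) <- genome_ids
    gene_ids <- unlist(lapply(seq_len(n_genomes), function(i)
      sprintf("%s_g%04d", genome_ids[i], seq_len(genes_per_genome[i]))),
      use.names = FALSE)
    gene_to_genome <- rep(genome_ids, genes_per_genome)
    names(gene_to_genome) <- gene_ids
    n_genes <- length(gene_ids)

    # simulated percent identity of each gene's best reference-genome hit
    gene_genome_identity <- pmin(100, pmax(80, rnorm(n_genes, 97, 1.5)))
    names(gene_genome_identity) <- gene_ids

    draw_map <- function(rate, labels) {
      if (rate <= 0 || length(labels) == 0L) return(character(0))
      pick <- runif(n_genes) < rate
      out <- sample(labels, sum(pick), replace = TRUE)
      names(out) <- gene_ids[pick]
      out
    }
    ko_pool <- sprintf("K%05d", seq_len(n_kos))
    gene_to_ko <- draw_map(rates$ko, ko_pool)
    gene_to_enzyme <- draw_map(rates$enzyme, TMA_LYASE_FAMILIES)
    gene_to_virus <- draw_map(rates$virus, sprintf("V%03d", seq_len(n_viruses)))

    assigned_kos <- unique(unname(gene_to_ko))
    module_map <- list()
    if (n_modules > 0L && length(assigned_kos) > 0L) {
      msz <- as.integer(module_size_range)
      for (i in seq_len(n_modules)) {
        k <- min(length(assigned_kos),
                 if (msz[1] == msz[2]) msz[1] else sample(seq(msz[1], msz[2]), 1L))
        module_map[[sprintf("M%04d", i)]] <- sort(sample(assigned_kos, k))
      }
    }

    structure(list(genome_ids = genome_ids,
                   gene_ids = gene_ids,
                   genes_per_genome = genes_per_genome,
                   gene_to_genome = gene_to_genome,
                   gene_genome_identity = gene_genome_identity,
                   gene_to_ko = gene_to_ko,
                   gene_to_enzyme = gene_to_enzyme,
                   gene_to_virus = gene_to_virus,
                   module_map = module_map,
                   seed = as.integer(seed)),
              class = "synthetic_catalog")
  })
}

#' Describe the generative community model for a synthetic cohort
#'
#' Collects the distributional knobs of the cohort simulator: log-normal
#' genome composition, per-genome case/control log2 fold changes, sequencing
#' depth, detection dropout, and linear clinical-index / drug-effect maps.
#' The cohort of the study this package is modeled on has no published
#' generative description, so these choices are explicit stand-ins (see the
#' methods vignette).
#'
#' @param catalog a `synthetic_catalog`.
#' @param baseline_log_abundance optional named numeric of log-abundance
#'   locations per genome; drawn `N(0, baseline_sd^2)` at simulation time
#'   when `NULL`.
#' @param baseline_sd sd of the drawn baseline when not supplied.
#' @param dispersion positive sd of the per-sample log-abundance noise.
#' @param case_log2_fold_change named numeric, log2 fold change applied to
#'   case samples per genome (genomes absent from the vector get 0).
#' @param sequencing_depth reads per sample (scalar or per-sample later).
#' @param zero_inflation fraction in `[0,1]` of gene-sample cells zeroed
#'   after the count draw (detection dropout).
#' @param gene_weight_sd sdlog of the fixed per-gene log-normal weight; genes
#'   of one genome stay proportional across samples up to count noise.
#' @param clinical_effect_map named list: index id -> `list(genome, slope,
#'   noise_sd)`; `slope = 0` yields a pure-noise index.
#' @param drug_effect_map named list: drug id -> `list(genome,
#'   log2_fold_change)`; applied on top of disease effects in treated cases.
#' @param drug_prevalence probability a case sample takes each drug.
#' @return a list of class `community_model`.
#' @export
community_model <- function(catalog,
                            baseline_log_abundance = NULL,
                            baseline_sd = 1.5,
                            dispersion = 0.7,
                            case_log2_fold_change = NULL,
                            sequencing_depth = 1e5,
                            zero_inflation = 0,
                            gene_weight_sd = 0.7,
                            clinical_effect_map = list(),
                            drug_effect_map = list(),
                            drug_prevalence = 0.5) {
  stopifnot(inherits(catalog, "synthetic_catalog"))
  if (dispersion <= 0) stop_input("dispersion must be > 0")
  if (sequencing_depth < 1) stop_input("sequencing_depth must be >= 1")
  if (zero_inflation < 0 || zero_inflation > 1)
    stop_input("zero_inflation must lie in [0, 1]")
  lfc <- stats::setNames(rep(0, length(catalog$genome_ids)), catalog$genome_ids)
  if (!is.null(case_log2_fold_change)) {
    if (is.null(names(case_log2_fold_change)))
      stop_input("case_log2_fold_change must be named by genome")
    unknown <- setdiff(names(case_log2_fold_change), catalog$genome_ids)
    if (length(unknown))
      stop_input("fold change on unknown genome(s): %s",
                 paste(unknown, collapse = ", "))
    if (any(!is.finite(case_log2_fold_change)))
      stop_input("fold changes must be finite")
    lfc[names(case_log2_fold_change)] <- case_log2_fold_change
  }
  for (d in drug_effect_map)
    if (!d[[1]] %in% catalog$genome_ids)
      stop_input("drug effect on unknown genome %s", d[[1]])
  for (ce in clinical_effect_map)
    if (!ce[[1]] %in% catalog$genome_ids)
      stop_input("clinical effect on unknown genome %s", ce[[1]])
  if (!is.null(baseline_log_abundance)) {
    if (!all(catalog$genome_ids %in% names(baseline_log_abundance)))
      stop_input("baseline_log_abundance must cover every genome")
    baseline_log_abundance <- baseline_log_abundance[catalog$genome_ids]
  }
  structure(list(baseline_log_abundance = baseline_log_abundance,
                 baseline_sd = baseline_sd,
                 dispersion = dispersion,
                 case_log2_fold_change = lfc,
                 sequencing_depth = sequencing_depth,
                 zero_inflation = zero_inflation,
                 gene_weight_sd = gene_weight_sd,
                 clinical_effect_map = clinical_effect_map,
                 drug_effect_map = drug_effect_map,
                 drug_prevalence = drug_prevalence),
            class = "community_model")
}

#' Simulate a case-control metagenomic cohort
#'
#' Draws per-sample genome abundances from the community model, distributes a
#' fixed sequencing depth over genes by a multinomial draw weighted by genome
#' abundance times a fixed per-gene weight (so genes of one genome co-vary,
#' the signal MLG binning exploits), applies case fold changes, per-case drug
#' effects and detection dropout, and generates clinical indices as linear
#' responses to the latent log abundance of their target genome plus noise.
#'
#' @param catalog a `synthetic_catalog`.
#' @param model a `community_model` built on the same catalog.
#' @param n_case,n_control positive sample counts per group.
#' @param seed integer seed; all outputs are reproducible given it.
#' @return list with `counts` (gene-by-sample integer matrix), `metadata`
#'   (data.frame: sample, group, subtype, one logical column per drug, one
#'   numeric column per clinical index) and `truth` (list: `true_bins`,
#'   `true_enriched`, `true_depleted`, `true_module_direction`,
#'   `true_clinical_pairs`, `true_drug_effects`).
#' @export
simulate_cohort <- function(catalog, model, n_case, n_control, seed = 1L) {
  stopifnot(inherits(catalog, "synthetic_catalog"),
            inherits(model, "community_model"))
  if (n_case < 1L || n_control < 1L)
    stop_input("n_case and n_control must be positive")
  n <- n_case + n_control
  genomes <- catalog$genome_ids
  genes <- catalog$gene_ids
  g_of <- catalog$gene_to_genome

  with_seed(seed, {
    base <- model$baseline_log_abundance %||%
      stats::setNames(rnorm(length(genomes), 0, model$baseline_sd), genomes)
    gene_w <- rlnorm(length(genes), 0, model$gene_weight_sd)
    names(gene_w) <- genes

    sample_ids <- c(sprintf("case_%03d", seq_len(n_case)),
                    sprintf("ctrl_%03d", seq_len(n_control)))
    group <- rep(c("case", "control"), c(n_case, n_control))

    # subtype split for cases mirrors a stable/unstable/acute clinical mix
    subtype <- rep(NA_character_, n)
    subtype[group == "case"] <- sample(c("stable_angina", "unstable_angina", "AMI"),
                                       n_case, replace = TRUE,
                                       prob = c(0.94, 0.037, 0.023))

    drugs <- names(model$drug_effect_map)
    drug_flags <- matrix(FALSE, n, length(drugs),
                         dimnames = list(sample_ids, drugs))
    for (d in drugs)
      drug_flags[group == "case", d] <- runif(n_case) < model$drug_prevalence

    # latent per-sample genome log abundance
    lat <- matrix(rnorm(length(genomes) * n, 0, model$dispersion),
                  length(genomes), n, dimnames = list(genomes, sample_ids))
    lat <- lat + base[genomes]
    is_case <- group == "case"
    lat[, is_case] <- lat[, is_case] + model$case_log2_fold_change[genomes] * log(2)
    for (d in drugs) {
      eff <- model$drug_effect_map[[d]]
      treated <- drug_flags[, d]
      lat[eff[[1]], treated] <- lat[eff[[1]], treated] + eff[[2]] * log(2)
    }

    # counts: multinomial over genes, weights = genome abundance x gene weight
    depth <- as.integer(round(model$sequencing_depth))
    counts <- matrix(0L, length(genes), n, dimnames = list(genes, sample_ids))
    gw <- gene_w
    for (j in seq_len(n)) {
      p <- exp(lat[g_of, j]) * gw
      counts[, j] <- rmultinom(1, depth, p / sum(p))[, 1]
    }
    if (model$zero_inflation > 0) {
      drop <- matrix(runif(length(counts)) < model$zero_inflation,
                     nrow(counts), ncol(counts))
      counts[drop] <- 0L
    }

    # clinical indices: linear in the latent log abundance of a target genome
    indices <- list()
    for (idx in names(model$clinical_effect_map)) {
      ce <- model$clinical_effect_map[[idx]]
      slope <- ce[[2]]
      noise_sd <- if (length(ce) >= 3) ce[[3]] else 1
      indices[[idx]] <- slope * lat[ce[[1]], ] + rnorm(n, 0, noise_sd)
    }

    metadata <- data.frame(sample = sample_ids, group = group,
                           subtype = subtype, stringsAsFactors = FALSE)
    for (d in drugs) metadata[[d]] <- drug_flags[, d]
    for (idx in names(indices)) metadata[[idx]] <- indices[[idx]]

    lfc <- model$case_log2_fold_change
    truth <- list(
      true_bins = g_of,
      true_enriched = names(lfc)[lfc > 0],
      true_depleted = names(lfc)[lfc < 0],
      true_module_direction = module_truth_direction(catalog, lfc),
      true_clinical_pairs = do.call(rbind, lapply(names(model$clinical_effect_map),
        function(idx) {
          ce <- model$clinical_effect_map[[idx]]
          if (ce[[2]] == 0) NULL else
            data.frame(genome = ce[[1]], index = idx, slope = ce[[2]],
                       stringsAsFactors = FALSE)
        })),
      true_drug_effects = model$drug_effect_map)
    stopifnot(length(intersect(truth$true_enriched, truth$true_depleted)) == 0L)

    list(counts = counts, metadata = metadata, truth = truth)
  })
}

# Per-module planted direction: average the case log2 fold change of the
# genomes hosting each member KO's genes (gene-count weighted); +/-1 when the
# mean shift is at least half a log2 unit, else 0.
module_truth_direction <- function(catalog, lfc, min_shift = 0.5) {
  if (length(catalog$module_map) == 0L) return(integer(0))
  ko_genome <- data.frame(ko = unname(catalog$gene_to_ko),
                          genome = catalog$gene_to_genome[names(catalog$gene_to_ko)],
                          stringsAsFactors = FALSE)
  ko_mean_lfc <- tapply(lfc[ko_genome$genome], ko_genome$ko, mean)
  vapply(catalog$module_map, function(kos) {
    v <- ko_mean_lfc[intersect(kos, names(ko_mean_lfc))]
    if (length(v) == 0L) return(0L)
    m <- mean(v)
    if (m >= min_shift) 1L else if (m <= -min_shift) -1L else 0L
  }, integer(1))
}
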