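# Pipeline configuration, input validation, and the end-to-end driver that
# chains simulate -> profiles -> mlg -> stats -> markers.

#' Default pipeline configuration
#'
#' Returns the full parameter tree of the pipeline with desk-scale defaults:
#' a 40-genome synthetic cohort of 60 cases and 60 controls with planted
#' enriched/depleted genomes, drug effects and clinical indices, and stage
#' parameters mirroring the analysis conventions (prevalence filter 10,
#' binning threshold 0.6 with >100-gene MLGs, q < 0.05, 999-permutation
#' Jensen-Shannon PERMANOVA, fivefold forests). Any element can be
#' overridden via `...` (named sublists are merged).
#'
#' @param ... named overrides, e.g. `simulate = list(n_case = 100)`.
#' @param seed master seed for the whole run.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., seed = 1L) {
  cfg <- list(
    seed = as.integer(seed),
    stages = c("simulate", "profiles", "mlg", "stats", "markers"),
    inputs = list(counts = NULL, metadata = NULL, gene_to_genome = NULL,
                  gene_to_ko = NULL, gene_to_enzyme = NULL,
                  gene_to_virus = NULL, module_map = NULL),
    simulate = list(n_genomes = 40L, genes_per_genome_range = c(100L, 200L),
                    n_case = 60L, n_control = 60L,
                    sequencing_depth = 1e6, dispersion = 0.7,
                    baseline_sd = 1.5, gene_weight_sd = 0.7,
                    zero_inflation = 0.05,
                    n_enriched = 5L, n_depleted = 5L, lfc = 2,
                    annotation_rates = list(ko = 0.4, enzyme = 0.02,
                                            virus = 0.03),
                    n_kos = 150L, n_modules = 20L,
                    drug_lfc = c(drug_A = 1.5, drug_B = 0),
                    n_clinical = 3L, clinical_slope = 1.5,
                    clinical_noise_sd = 0.8, n_clinical_null = 2L),
    profiles = list(min_samples = 10L),
    mlg = list(cc_threshold = 0.6, min_genes = 100L),
    stats = list(q_cut = 0.05, network_cc_min = 0.3, n_perm = 999L,
                 reporter_min_samples = 5L, n_background = 1000L),
    markers = list(folds = 5L, repeats = 2L, max_panel = 25L,
                   num_trees = 200L,
                   clinical_n_perm = 500L, clinical_repeats = 1L,
                   clinical_num_trees = 100L,
                   drug_repeats = 2L, drug_num_trees = 100L))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  # YAML deserializes named vectors as lists; normalize scalar-map fields
  cfg$simulate$drug_lfc <- unlist(cfg$simulate$drug_lfc)
  cfg$simulate$genes_per_genome_range <-
    as.integer(unlist(cfg$simulate$genes_per_genome_range))
  cfg$stages <- as.character(unlist(cfg$stages))
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The round trip is lossless for every parameter the pipeline consumes.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, c(raw[setdiff(names(raw), "seed")],
                             seed = raw$seed %||% 1L))
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  raw <- unclass(config)
  # named atomic vectors serialize as sequences (names lost); use maps
  if (!is.null(names(raw$simulate$drug_lfc)))
    raw$simulate$drug_lfc <- as.list(raw$simulate$drug_lfc)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Validate pipeline inputs
#'
#' Structural checks on a counts matrix and sample metadata: duplicate ids,
#' negative or non-numeric values, and matrix/metadata sample alignment.
#' Inputs may be in-memory objects or TSV paths. Nothing is mutated.
#'
#' @param counts matrix or TSV path.
#' @param metadata data.frame (with `sample` column) or TSV path.
#' @return data.frame of findings (`level`, `code`, `id`, `message`); zero
#'   rows when clean.
#' @export
validate_inputs <- function(counts, metadata = NULL) {
  findings <- list()
  note <- function(level, code, id, message)
    findings[[length(findings) + 1L]] <<-
      data.frame(level = level, code = code, id = id, message = message,
                 stringsAsFactors = FALSE)
  if (is.character(counts)) {
    if (!file.exists(counts))
      stop_input("cannot read counts file: %s", counts)
    counts <- read_abundance_tsv(counts)
  }
  if (is.character(metadata)) {
    if (!file.exists(metadata))
      stop_input("cannot read metadata file: %s", metadata)
    metadata <- read.delim(metadata, stringsAsFactors = FALSE)
  }
  dup <- rownames(counts)[duplicated(rownames(counts))]
  for (g in unique(dup)) note("error", "duplicate_gene", g,
                              "duplicated gene id in matrix")
  dups <- colnames(counts)[duplicated(colnames(counts))]
  for (s in unique(dups)) note("error", "duplicate_sample", s,
                               "duplicated sample id in matrix")
  if (any(counts < 0))
    note("error", "negative_values", "", "matrix contains negative entries")
  if (any(!is.finite(counts)))
    note("error", "nonfinite_values", "", "matrix contains non-finite entries")
  if (!is.null(metadata)) {
    if (!"sample" %in% names(metadata)) {
      note("error", "no_sample_column", "", "metadata lacks a sample column")
    } else {
      for (s in setdiff(colnames(counts), metadata$sample))
        note("error", "sample_missing_metadata", s,
             "matrix sample absent from metadata")
      for (s in setdiff(metadata$sample, colnames(counts)))
        note("warning", "sample_missing_matrix", s,
             "metadata sample absent from matrix")
    }
  }
  if (length(findings) == 0L)
    return(data.frame(level = character(0), code = character(0),
                      id = character(0), message = character(0)))
  do.call(rbind, findings)
}

simulate_stage <- function(cfg) {
  sc <- cfg$simulate
  catalog <- generate_catalog(sc$n_genomes, sc$genes_per_genome_range,
                              annotation_rates = sc$annotation_rates,
                              n_kos = sc$n_kos, n_modules = sc$n_modules,
                              seed = child_seed(cfg$seed, 1))
  genomes <- catalog$genome_ids
  lfc <- stats::setNames(rep(0, length(genomes)), genomes)
  if (sc$n_enriched > 0) lfc[seq_len(sc$n_enriched)] <- sc$lfc
  if (sc$n_depleted > 0)
    lfc[sc$n_enriched + seq_len(sc$n_depleted)] <- -sc$lfc
  null_genomes <- genomes[lfc == 0]
  drug_map <- list()
  dl <- sc$drug_lfc
  for (i in seq_along(dl))
    drug_map[[names(dl)[i]]] <- list(null_genomes[(i %% length(null_genomes)) + 1L],
                                     unname(dl[i]))
  clin_map <- list()
  if (sc$n_clinical > 0)
    for (i in seq_len(sc$n_clinical))
      clin_map[[sprintf("index_%02d", i)]] <-
        list(genomes[(i - 1L) %% length(genomes) + 1L], sc$clinical_slope,
             sc$clinical_noise_sd)
  if (sc$n_clinical_null > 0)
    for (i in seq_len(sc$n_clinical_null))
      clin_map[[sprintf("index_null_%02d", i)]] <-
        list(genomes[1], 0, 1)
  model <- community_model(catalog,
                           baseline_sd = sc$baseline_sd,
                           dispersion = sc$dispersion,
                           case_log2_fold_change = lfc,
                           sequencing_depth = sc$sequencing_depth,
                           zero_inflation = sc$zero_inflation,
                           gene_weight_sd = sc$gene_weight_sd,
                           clinical_effect_map = clin_map,
                           drug_effect_map = drug_map)
  cohort <- simulate_cohort(catalog, model, sc$n_case, sc$n_control,
                            seed = child_seed(cfg$seed, 2))
  list(catalog = catalog, model = model, cohort = cohort)
}

#' Run the full MWAS pipeline
#'
#' Executes the enabled stages in dependency order: `simulate` (or load the
#' configured input files), `profiles` (relative abundance, prevalence
#' filter, genome/KO/enzyme/virus summaries), `mlg` (binning, quantification,
#' taxonomy), `stats` (differential MLGs, case/control co-occurrence
#' networks, PCA, dbRDA, Jensen-Shannon PERMANOVA, reporter scores) and
#' `markers` (RFCV classifier with ROC, TMA-lyase classifier, clinical-index
#' associations, medication analysis). Every declared output file is written
#' under `out_dir`, together with the resolved configuration and a
#' machine-readable run report. Reruns with an identical configuration
#' produce identical outputs.
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if absent).
#' @return the run report, invisibly (a list; also written as
#'   `run_report.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  write_pipeline_config(config, pth("resolved_config.yaml"))
  stages <- config$stages
  report <- list(package_version = as.character(utils::packageVersion("mlgmwas")),
                 seed = config$seed, stages_run = stages,
                 stages_skipped = setdiff(c("simulate", "profiles", "mlg",
                                            "stats", "markers"), stages),
                 counts = list())
  cnt <- function(k, v) report$counts[[k]] <<- v

  # ---- inputs -------------------------------------------------------------
  ann <- list()
  truth <- NULL
  if ("simulate" %in% stages) {
    sim <- simulate_stage(config)
    counts <- sim$cohort$counts
    metadata <- sim$cohort$metadata
    truth <- sim$cohort$truth
    catalog <- sim$catalog
    ann$genome <- data.frame(gene_id = names(catalog$gene_to_genome),
                             feature_id = unname(catalog$gene_to_genome),
                             identity = unname(catalog$gene_genome_identity),
                             stringsAsFactors = FALSE)
    ann$ko <- catalog$gene_to_ko
    ann$enzyme <- catalog$gene_to_enzyme
    ann$virus <- catalog$gene_to_virus
    module_map <- catalog$module_map
    write_abundance_tsv(counts, pth("counts.tsv"), "gene_id")
    write.table(metadata, pth("metadata.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_annotation_tsv(ann$genome, pth("gene_to_genome.tsv"))
    write_annotation_tsv(ann$ko, pth("gene_to_ko.tsv"))
    write_annotation_tsv(ann$enzyme, pth("gene_to_enzyme.tsv"))
    write_annotation_tsv(ann$virus, pth("gene_to_virus.tsv"))
    write_module_map_tsv(module_map, pth("module_map.tsv"))
    write_truth_json(truth, pth("truth.json"))
    cnt("n_genes", nrow(counts)); cnt("n_samples", ncol(counts))
  } else {
    ip <- config$inputs
    if (is.null(ip$counts) || is.null(ip$metadata))
      stop_input("stage 'simulate' disabled and no input counts/metadata configured")
    counts <- read_abundance_tsv(ip$counts)
    metadata <- read.delim(ip$metadata, stringsAsFactors = FALSE)
    for (a in c("gene_to_genome", "gene_to_ko", "gene_to_enzyme",
                "gene_to_virus"))
      if (!is.null(ip[[a]]))
        ann[[sub("gene_to_", "", a)]] <- read_annotation_tsv(ip[[a]])
    module_map <- if (!is.null(ip$module_map))
      read_module_map_tsv(ip$module_map) else list()
    cnt("n_genes", nrow(counts)); cnt("n_samples", ncol(counts))
  }
  v <- validate_inputs(counts, metadata)
  if (any(v$level == "error"))
    stop_input("input validation failed: %s (%s)", v$code[1], v$id[1])
  groups <- factor(metadata$group, levels = c("case", "control"))

  # ---- profiles -----------------------------------------------------------
  if (!"profiles" %in% stages) {
    if (length(intersect(c("mlg", "stats", "markers"), stages)))
      stop_input("stage 'profiles' is required by later stages but disabled")
    write_report(report, pth("run_report.json"))
    return(invisible(report))
  }
  relab <- relative_abundance(counts)
  gene_prof <- filter_low_occurrence(relab, config$profiles$min_samples)
  prof <- list()
  for (a in names(ann))
    prof[[a]] <- aggregate_features(relab, ann[[a]])
  write_abundance_tsv(gene_prof, pth("gene_abundance.tsv"), "gene_id")
  for (a in names(prof))
    write_abundance_tsv(prof[[a]], pth(sprintf("%s_abundance.tsv", a)), a)
  cnt("n_genes_after_prevalence", nrow(gene_prof))

  # ---- mlg ----------------------------------------------------------------
  mlg_ab <- NULL
  if ("mlg" %in% stages) {
    mlgs <- build_mlgs(gene_prof, config$mlg$cc_threshold,
                       config$mlg$min_genes)
    if (!is.null(ann$genome))
      mlgs <- assign_taxonomy_all(mlgs, ann$genome)
    mlg_ab <- mlg_abundance(mlgs, gene_prof)
    write.table(mlg_membership(mlgs), pth("mlg_membership.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_abundance_tsv(mlg_ab, pth("mlg_abundance.tsv"), "mlg_id")
    tax <- do.call(rbind, lapply(mlgs, function(x) {
      tg <- x$taxonomy$top_genomes
      if (is.null(tg) || nrow(tg) == 0L)
        return(data.frame(mlg_id = x$mlg_id, assigned_taxon = NA_character_,
                          genome = NA_character_, fraction = NA_real_,
                          mean_identity = NA_real_, stringsAsFactors = FALSE))
      data.frame(mlg_id = x$mlg_id,
                 assigned_taxon = x$taxonomy$assigned_taxon,
                 genome = tg$genome, fraction = tg$fraction,
                 mean_identity = tg$mean_identity, stringsAsFactors = FALSE)
    })) %||% data.frame()
    write.table(tax, pth("mlg_taxonomy.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cnt("n_mlgs", length(mlgs))
  } else if ("stats" %in% stages || "markers" %in% stages) {
    stop_input("stage 'mlg' is required by later stages but disabled")
  }

  # ---- stats --------------------------------------------------------------
  diff_mlg <- NULL
  if ("stats" %in% stages) {
    st <- config$stats
    diff_mlg <- differential_abundance(mlg_ab, groups, st$q_cut)
    write.table(diff_mlg, pth("differential_mlgs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    cnt("n_mlgs_significant", sum(diff_mlg$significant))
    sig <- diff_mlg$feature_id[diff_mlg$significant]
    for (side in c("case", "control")) {
      sub <- colnames(mlg_ab)[groups == side]
      edges <- if (length(sig) >= 2L)
        cooccurrence_network(mlg_ab[sig, , drop = FALSE], sub,
                             st$network_cc_min)
      else data.frame(feature_a = character(0), feature_b = character(0),
                      cc = numeric(0), sign = character(0),
                      weight_class = character(0))
      write.table(edges, pth(sprintf("network_%s.tsv", side)), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      if (nrow(edges))
        write_network_graphml(edges, pth(sprintf("network_%s.graphml", side)))
      cnt(sprintf("n_network_edges_%s", side), nrow(edges))
    }
    genus_prof <- prof$genome %||% gene_prof
    pca <- pca_ordination(genus_prof)
    write_abundance_tsv(t(pca$scores), pth("pca_scores.tsv"), "sample")
    write_abundance_tsv(pca$loadings, pth("pca_loadings.tsv"), "feature")
    bc <- distance_matrix(genus_prof, "bray_curtis")
    cap <- dbrda(bc, groups, features = genus_prof)
    write_abundance_tsv(t(as.matrix(cap$scores)), pth("dbrda_scores.tsv"),
                        "sample")
    jsd <- distance_matrix(mlg_ab, "jensen_shannon")
    pmv <- permanova(jsd, groups, n_perm = st$n_perm,
                     seed = child_seed(config$seed, 31),
                     factor_id = "disease_status")
    write.table(data.frame(factor_id = pmv$factor_id,
                           pseudo_F = pmv$pseudo_F,
                           r_squared = pmv$r_squared,
                           p_value = pmv$p_value, n_perm = pmv$n_perm),
                pth("permanova.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    cnt("permanova_p", pmv$p_value)
    if (!is.null(prof$ko) && nrow(prof$ko) >= 2L && length(module_map)) {
      rep_sc <- suppressWarnings(
        reporter_scores(prof$ko, groups, module_map,
                        min_samples = st$reporter_min_samples,
                        n_background = st$n_background,
                        seed = child_seed(config$seed, 32)))
      write.table(rep_sc, pth("reporter_scores.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      cnt("n_modules_scored", nrow(rep_sc))
      cnt("n_modules_flagged", sum(rep_sc$direction != "none"))
    }
  }

  # ---- markers ------------------------------------------------------------
  if ("markers" %in% stages) {
    mk <- config$markers
    sel <- rfcv_select(mlg_ab, groups, folds = mk$folds,
                       repeats = mk$repeats, max_panel = mk$max_panel,
                       seed = child_seed(config$seed, 41),
                       num_trees = mk$num_trees)
    roc <- roc_analysis(sel$probabilities, groups)
    write.table(data.frame(rank = seq_along(sel$ranked_features),
                           feature = sel$ranked_features,
                           in_panel = sel$ranked_features %in% sel$chosen_panel),
                pth("marker_panel.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(data.frame(sample = names(sel$probabilities),
                           probability = sel$probabilities,
                           label = as.character(groups)),
                pth("marker_probabilities.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(roc$roc_points, pth("roc_points.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(auc = roc$auc, ci_low = roc$ci_low,
                              ci_high = roc$ci_high,
                              youden_index = roc$youden_index,
                              youden_cutoff = roc$youden_cutoff,
                              panel_size = length(sel$chosen_panel)),
                         pth("roc_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    cnt("panel_size", length(sel$chosen_panel))
    cnt("classifier_auc", roc$auc)

    if (!is.null(prof$enzyme) && nrow(prof$enzyme) >= 1L) {
      ez <- enzyme_classifier(prof$enzyme, groups, folds = mk$folds,
                              repeats = mk$repeats,
                              seed = child_seed(config$seed, 42),
                              num_trees = mk$num_trees)
      jsonlite::write_json(list(auc = ez$roc$auc,
                                youden_index = ez$roc$youden_index),
                           pth("enzyme_roc_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      cnt("enzyme_auc", ez$roc$auc)
    }

    idx_cols <- grep("^index_", names(metadata), value = TRUE)
    if (length(idx_cols)) {
      assoc <- suppressWarnings(
        clinical_association(mlg_ab, metadata[, idx_cols, drop = FALSE],
                             n_perm = mk$clinical_n_perm,
                             folds = mk$folds, repeats = mk$clinical_repeats,
                             num_trees = mk$clinical_num_trees,
                             seed = child_seed(config$seed, 43)))
      write.table(assoc, pth("clinical_associations.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      cnt("n_clinical_associations", nrow(assoc))
    }

    drug_cols <- names(metadata)[vapply(metadata, is.logical, NA)]
    if (length(drug_cols)) {
      med <- medication_analysis(mlg_ab, groups,
                                 metadata[, drug_cols, drop = FALSE],
                                 folds = mk$folds, repeats = mk$drug_repeats,
                                 num_trees = mk$drug_num_trees,
                                 n_perm = config$stats$n_perm,
                                 seed = child_seed(config$seed, 44))
      write.table(med$classifiers, pth("drug_classifiers.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(med$permanova, pth("drug_permanova.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      cnt("n_drugs", length(drug_cols))
    }
  }

  write_report(report, pth("run_report.json"))
  invisible(report)
}

write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
}
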