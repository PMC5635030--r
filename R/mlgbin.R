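# Metagenomic linkage groups: co-abundance gene binning, MLG quantification,
# and taxonomy assignment by reference-genome vote.
#
# Genes from one microbial genome are physically linked, so their abundances
# co-vary across samples. The binning procedure here builds a gene graph with
# edges wherever pairwise Spearman correlation reaches `cc_threshold`, takes
# connected components, and refines each component by average-linkage
# agglomeration on (1 - cc) with a merge ceiling of (1 - cc_threshold).
# Everything is deterministic: genes are canonically ordered by id before
# clustering and ties break lexicographically.

#' Cluster genes into metagenomic linkage groups
#'
#' @param m prevalence-filtered gene-by-sample relative-abundance matrix,
#'   at least 3 samples.
#' @param cc_threshold Spearman correlation threshold in (0,1) for linking
#'   two genes (default 0.6).
#' @param min_genes strict minimum size: only clusters with more than
#'   `min_genes` genes are returned (default 100, so reported MLGs contain
#'   over 100 genes).
#' @param seed accepted for interface symmetry; the procedure is
#'   deterministic and does not consume randomness.
#' @param block_size genes per block in the blockwise correlation pass
#'   (memory/speed trade-off only).
#' @param refine_max largest component refined by hierarchical agglomeration;
#'   larger components are kept whole with a warning.
#' @return list of MLG records (class `mlg_set`); each has `mlg_id`,
#'   `gene_ids` (sorted), `size`, and `taxonomy` (filled by
#'   [assign_taxonomy()]). Ids are assigned in decreasing size order.
#' @export
build_mlgs <- function(m, cc_threshold = 0.6, min_genes = 100L, seed = NULL,
                       block_size = 2000L, refine_max = 5000L) {
  assert_abundance(m)
  if (!is.numeric(cc_threshold) || cc_threshold <= 0 || cc_threshold >= 1)
    stop_input("cc_threshold must lie strictly inside (0, 1)")
  if (ncol(m) < 3L) stop_input("at least 3 samples are required for binning")

  # drop samples with zero total, canonical gene order
  m <- m[, colSums(m) > 0, drop = FALSE]
  m <- m[order(rownames(m)), , drop = FALSE]
  p <- nrow(m)
  if (p < 2L) return(structure(list(), class = "mlg_set"))

  # row-wise midranks, centered and norm-scaled so crossprod = Spearman cc
  r <- t(apply(m, 1L, rank))
  r <- r - rowMeans(r)
  nrm <- sqrt(rowSums(r * r))
  ok <- nrm > 0                       # constant genes carry no signal
  r[ok, ] <- r[ok, , drop = FALSE] / nrm[ok]
  r[!ok, ] <- 0

  # blockwise correlation; collect edges with cc >= threshold (i < j)
  edges_from <- integer(0); edges_to <- integer(0)
  starts <- seq(1L, p, by = block_size)
  for (s in starts) {
    e <- min(s + block_size - 1L, p)
    cc <- r[s:e, , drop = FALSE] %*% t(r)
    hit <- which(cc >= cc_threshold, arr.ind = TRUE)
    gi <- hit[, 1L] + s - 1L
    gj <- hit[, 2L]
    keep <- gi < gj
    edges_from <- c(edges_from, gi[keep])
    edges_to <- c(edges_to, gj[keep])
  }

  g <- igraph::make_empty_graph(n = p, directed = FALSE)
  if (length(edges_from))
    g <- igraph::add_edges(g, rbind(edges_from, edges_to))
  comp <- igraph::components(g)$membership

  # refine components: average linkage on (1 - cc), cut at 1 - threshold
  clusters <- list()
  for (cid in sort(unique(comp))) {
    idx <- which(comp == cid)
    if (length(idx) <= 2L) {
      clusters[[length(clusters) + 1L]] <- idx
      next
    }
    if (length(idx) > refine_max) {
      warning(sprintf("component of %d genes exceeds refine_max; kept whole",
                      length(idx)))
      clusters[[length(clusters) + 1L]] <- idx
      next
    }
    cc_sub <- r[idx, , drop = FALSE] %*% t(r[idx, , drop = FALSE])
    h <- hclust(stats::as.dist(1 - cc_sub), method = "average")
    cut <- cutree(h, h = 1 - cc_threshold)
    for (k in sort(unique(cut)))
      clusters[[length(clusters) + 1L]] <- idx[cut == k]
  }

  sizes <- lengths(clusters)
  keep <- sizes > min_genes
  clusters <- clusters[keep]
  if (length(clusters) == 0L) return(structure(list(), class = "mlg_set"))
  # order by size desc, then first gene id, for stable labeling
  first_gene <- vapply(clusters, function(ix) rownames(m)[min(ix)], "")
  ord <- order(-lengths(clusters), first_gene)
  clusters <- clusters[ord]
  out <- lapply(seq_along(clusters), function(i)
    list(mlg_id = sprintf("MLG%04d", i),
         gene_ids = sort(rownames(m)[clusters[[i]]]),
         size = length(clusters[[i]]),
         taxonomy = NULL))
  structure(out, class = "mlg_set")
}

#' Sum member-gene abundances into MLG abundance profiles
#'
#' The relative abundance of each MLG in each sample is the sum of the
#' relative abundances of its constituent genes.
#'
#' @param mlgs `mlg_set` (or plain list of MLG records).
#' @param m gene-by-sample abundance matrix containing every member gene.
#' @return MLG-by-sample abundance matrix.
#' @export
mlg_abundance <- function(mlgs, m) {
  assert_abundance(m)
  if (length(mlgs) == 0L)
    return(matrix(0, 0, ncol(m), dimnames = list(character(0), colnames(m))))
  out <- matrix(0, length(mlgs), ncol(m),
                dimnames = list(vapply(mlgs, `[[`, "", "mlg_id"), colnames(m)))
  for (i in seq_along(mlgs)) {
    miss <- setdiff(mlgs[[i]]$gene_ids, rownames(m))
    if (length(miss))
      stop_input("gene %s of %s missing from the abundance matrix",
                 miss[1], mlgs[[i]]$mlg_id)
    out[i, ] <- colSums(m[mlgs[[i]]$gene_ids, , drop = FALSE])
  }
  out
}

#' Assign MLG taxonomy by reference-genome vote
#'
#' Each member gene votes for the reference genome it is annotated to; the
#' MLG is assigned a taxon only when one genome covers strictly more than
#' half of its genes. The top three genomes are always reported with the
#' fraction of genes covered and the mean alignment identity.
#'
#' @param mlg one MLG record (from [build_mlgs()]).
#' @param gene_taxa annotation map gene -> reference genome, optionally with
#'   an `identity` column (percent); may cover only part of the genes.
#' @param species_identity_min optional mean-identity floor (percent) that a
#'   winning genome must additionally reach; `NULL` (default) disables it.
#' @return list with `assigned_taxon` (label or `NA`) and `top_genomes`
#'   (data.frame genome / fraction / mean_identity, at most three rows,
#'   ordered by fraction).
#' @export
assign_taxonomy <- function(mlg, gene_taxa, species_identity_min = NULL) {
  ann <- as_annotation(gene_taxa)
  ann <- ann[ann$gene_id %in% mlg$gene_ids, , drop = FALSE]
  if (nrow(ann) == 0L)
    return(list(assigned_taxon = NA_character_,
                top_genomes = data.frame(genome = character(0),
                                         fraction = numeric(0),
                                         mean_identity = numeric(0))))
  frac <- tapply(ann$gene_id, ann$feature_id, length) / mlg$size
  mid <- tapply(ann$identity, ann$feature_id, function(x) mean(x, na.rm = TRUE))
  tab <- data.frame(genome = names(frac), fraction = as.numeric(frac),
                    mean_identity = as.numeric(mid[names(frac)]),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$fraction, tab$genome), , drop = FALSE]
  rownames(tab) <- NULL
  top <- head(tab, 3L)
  lead <- tab[1L, ]
  assigned <- if (lead$fraction > 0.5 &&
                  (is.null(species_identity_min) ||
                   (is.finite(lead$mean_identity) &&
                    lead$mean_identity >= species_identity_min)))
    lead$genome else NA_character_
  list(assigned_taxon = assigned, top_genomes = top)
}

#' Annotate every MLG in a set with taxonomy
#'
#' @param mlgs `mlg_set`.
#' @inheritParams assign_taxonomy
#' @return the `mlg_set` with each record's `taxonomy` filled in.
#' @export
assign_taxonomy_all <- function(mlgs, gene_taxa, species_identity_min = NULL) {
  for (i in seq_along(mlgs))
    mlgs[[i]]$taxonomy <- assign_taxonomy(mlgs[[i]], gene_taxa,
                                          species_identity_min)
  mlgs
}

#' Export MLG membership as a two-column table
#'
#' @param mlgs `mlg_set`.
#' @return data.frame with `mlg_id`, `gene_id`.
#' @export
mlg_membership <- function(mlgs) {
  if (length(mlgs) == 0L)
    return(data.frame(mlg_id = character(0), gene_id = character(0)))
  do.call(rbind, lapply(mlgs, function(x)
    data.frame(mlg_id = x$mlg_id, gene_id = x$gene_ids,
               stringsAsFactors = FALSE)))
}
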