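# TSV / JSON adapters for matrices, annotation maps and module maps.

#' Read a feature-by-sample abundance (or count) matrix from TSV
#'
#' First column = feature ids, header row = sample ids.
#'
#' @param path TSV file.
#' @return numeric matrix with dimnames.
#' @export
read_abundance_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_input("%s: need an id column plus samples", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param m matrix with dimnames.
#' @param path output file.
#' @param id_col header of the id column.
#' @export
write_abundance_tsv <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an annotation map (gene -> feature) from TSV
#'
#' Expects columns `gene_id` and `feature_id`, optional `identity`/`score`.
#'
#' @param path TSV file.
#' @return annotation data.frame.
#' @export
read_annotation_tsv <- function(path) {
  as_annotation(read.delim(path, stringsAsFactors = FALSE))
}

#' Write an annotation map as TSV
#'
#' @param ann annotation data.frame or named character vector.
#' @param path output file.
#' @export
write_annotation_tsv <- function(ann, path) {
  write.table(as_annotation(ann), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a module -> KO membership map from TSV
#'
#' Two columns: `module_id`, `ko_id` (one KO per row).
#'
#' @param path TSV file.
#' @return named list of KO character vectors.
#' @export
read_module_map_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("module_id", "ko_id") %in% names(df)))
    stop_input("%s: need columns module_id and ko_id", path)
  split(as.character(df$ko_id), df$module_id)
}

#' Write a module map as TSV
#'
#' @param module_map named list of KO vectors.
#' @param path output file.
#' @export
write_module_map_tsv <- function(module_map, path) {
  df <- data.frame(module_id = rep(names(module_map), lengths(module_map)),
                   ko_id = unlist(module_map, use.names = FALSE),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BLAST outfmt-6-style hit table
#'
#' @param path tabular file without header.
#' @param columns names for the columns present, which must include
#'   `gene_id`, `target_id`, `identity`, `score` (default: the six-column
#'   qseqid/sseqid/pident/evalue/bitscore layout).
#' @return data.frame usable with [filter_best_hits()].
#' @export
read_hit_table <- function(path, columns = c("gene_id", "target_id",
                                             "identity", "length",
                                             "evalue", "score")) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < length(columns))
    stop_input("%s: expected %d columns", path, length(columns))
  names(df)[seq_along(columns)] <- columns
  df
}

#' Serialize a ground-truth record as JSON
#'
#' @param truth the `truth` element of [simulate_cohort()] output.
#' @param path output file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
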