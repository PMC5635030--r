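# Internal helpers shared across modules.

#' @importFrom stats cor cutree dist fisher.test hclust median p.adjust
#'   prcomp qnorm quantile rbinom rlnorm rmultinom rnorm runif sd var
#'   wilcox.test cmdscale complete.cases model.matrix
#' @importFrom utils head read.delim write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# run expr with a private RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# derive a child seed, kept inside 32-bit integer range
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

assert_abundance <- function(m, what = "abundance matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop_input("%s must be a numeric matrix", what)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop_input("%s must carry feature rownames and sample colnames", what)
  if (anyDuplicated(rownames(m)))
    stop_input("%s has duplicated feature ids", what)
  if (anyDuplicated(colnames(m)))
    stop_input("%s has duplicated sample ids", what)
  if (any(m < 0)) stop_input("%s has negative entries", what)
  invisible(m)
}

assert_two_groups <- function(groups, n) {
  groups <- as.factor(groups)
  if (length(groups) != n)
    stop_input("group labels (%d) do not match the number of samples (%d)",
               length(groups), n)
  if (nlevels(droplevels(groups)) != 2L)
    stop_input("exactly two group levels are required")
  droplevels(groups)
}

# normalize an annotation (gene -> feature) into a two/four column data.frame
as_annotation <- function(ann) {
  if (is.data.frame(ann)) {
    need <- c("gene_id", "feature_id")
    if (!all(need %in% names(ann)))
      stop_input("annotation data.frame needs columns gene_id and feature_id")
    out <- data.frame(gene_id = as.character(ann$gene_id),
                      feature_id = as.character(ann$feature_id),
                      identity = if ("identity" %in% names(ann))
                        as.numeric(ann$identity) else rep(NA_real_, nrow(ann)),
                      score = if ("score" %in% names(ann))
                        as.numeric(ann$score) else rep(NA_real_, nrow(ann)),
                      stringsAsFactors = FALSE)
  } else if (is.character(ann) && !is.null(names(ann))) {
    out <- data.frame(gene_id = names(ann), feature_id = unname(ann),
                      identity = NA_real_, score = NA_real_,
                      stringsAsFactors = FALSE)
  } else {
    stop_input("annotation must be a data.frame or a named character vector")
  }
  if (anyDuplicated(out$gene_id))
    stop_input("annotation assigns more than one feature to some gene")
  out
}
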