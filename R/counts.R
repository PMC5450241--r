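#' Coerce a counts table to a gene-by-sample matrix
#'
#' User-facing functions in pupdevo accept counts either as a numeric matrix
#' with gene identifiers as row names, or as a data frame whose first column
#' (named `gene_id`) holds the identifiers and whose remaining columns are
#' samples. This helper normalises both to an integer-valued matrix.
#'
#' @param counts A matrix or data frame of non-negative counts.
#' @return Numeric matrix, genes in rows, with `dimnames` set.
#' @export
as_count_matrix <- function(counts) {
  if (is.matrix(counts)) {
    m <- counts
    if (is.null(rownames(m))) {
      abort("count matrix must have gene identifiers as row names")
    }
  } else if (is.data.frame(counts)) {
    if (!"gene_id" %in% names(counts)) {
      abort("counts data frame must have a 'gene_id' column")
    }
    ids <- as.character(counts$gene_id)
    m <- as.matrix(counts[setdiff(names(counts), "gene_id")])
    rownames(m) <- ids
  } else {
    abort("`counts` must be a matrix or a data frame")
  }
  if (anyDuplicated(rownames(m))) abort("duplicate gene identifiers")
  if (anyDuplicated(colnames(m))) abort("duplicate sample identifiers")
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) abort("counts contain missing or non-numeric values")
  if (any(m < 0)) abort("counts must be non-negative")
  m
}

#' Convert a count matrix to a tibble
#'
#' @param m Gene-by-sample matrix.
#' @return Tibble with a `gene_id` column followed by one column per sample.
#' @export
counts_tbl <- function(m) {
  dplyr::bind_cols(tibble(gene_id = rownames(m)), as_tibble(m))
}

# Restrict a matrix and sample sheet to the samples of one stage, keeping
# sheet order.
subset_stage <- function(m, samples, stage) {
  keep <- samples$stage == stage
  if (!any(keep)) abort(paste0("no samples for stage '", stage, "'"))
  sub <- samples[keep, , drop = FALSE]
  list(counts = m[, sub$sample_id, drop = FALSE], samples = sub)
}
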