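# Plain-text interchange: counts TSV, sample sheet CSV, DE results TSV,
# GMT gene-set collections, RNK ranked lists.

#' Write / read a counts matrix as TSV
#'
#' Tab-separated, one header row of sample identifiers, first column
#' `gene_id`.
#'
#' @param m Count matrix.
#' @param path Output file.
#' @export
write_counts <- function(m, path) {
  readr::write_tsv(counts_tbl(m), path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  as_count_matrix(as.data.frame(tb))
}

#' Write / read the sample sheet as CSV
#'
#' Columns `sample_id`, `taxon`, `stage`, `replicate`, `pair_id`.
#'
#' @param samples Sample sheet tibble.
#' @param path Output file.
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_csv(samples, path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(replicate = readr::col_integer(),
                                          .default = readr::col_character()))
}

#' Write a differential-expression result table
#'
#' Columns `gene_id`, `logFC`, `logCPM`, `PValue`, `FDR` (names are stable
#' for downstream parsing).
#'
#' @param result [test_pairwise()] tibble.
#' @param path Output file.
#' @export
write_de_table <- function(result, path) {
  readr::write_tsv(result[, c("gene_id", "logFC", "logCPM", "PValue", "FDR")],
                   path)
}

#' Read / write GMT gene-set collections
#'
#' Standard GMT: one set per line — name, description, then members,
#' tab-separated.
#'
#' @param path GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) abort("malformed GMT line (need name, description, members)")
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(names(sets))) abort("duplicate gene-set names in GMT")
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @param description Per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (any(lengths(sets) == 0)) abort("empty gene set in collection")
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read / write RNK ranked lists
#'
#' Two tab-separated columns: gene identifier, score.
#'
#' @param ranked Tibble `gene_id`, `score`.
#' @param path RNK file.
#' @export
write_rnk <- function(ranked, path) {
  readr::write_tsv(ranked[, c("gene_id", "score")], path, col_names = FALSE)
}

#' @rdname write_rnk
#' @export
read_rnk <- function(path) {
  readr::read_tsv(path, col_names = c("gene_id", "score"),
                  show_col_types = FALSE)
}
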