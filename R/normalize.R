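#' Remove mitochondrial and pseudogene entries
#'
#' Drops genes flagged for exclusion (typically mitochondrial genes and
#' annotated pseudogenes) before any filtering or testing. Row order of the
#' remaining genes is preserved.
#'
#' @param counts Count matrix or counts data frame (see [as_count_matrix()]).
#' @param gene_flags Data frame with columns `gene_id` and `exclude`
#'   (logical), or a character vector of gene identifiers to drop.
#' @return Count matrix without the flagged genes.
#' @export
remove_excluded_genes <- function(counts, gene_flags) {
  m <- as_count_matrix(counts)
  if (is.data.frame(gene_flags)) {
    drop_ids <- gene_flags$gene_id[as.logical(gene_flags$exclude)]
  } else {
    drop_ids <- as.character(gene_flags)
  }
  unknown <- setdiff(drop_ids, rownames(m))
  if (length(unknown) > 0) {
    warn(sprintf("%d flagged gene(s) not present in the matrix (e.g. %s)",
                 length(unknown), unknown[1]))
  }
  m[!rownames(m) %in% drop_ids, , drop = FALSE]
}

#' Counts per million
#'
#' CPM for each gene and sample: `count / (library size * factor) * 1e6`.
#' When TMM factors are supplied the denominator is the effective library
#' size; otherwise raw column totals are used.
#'
#' @param counts Count matrix or counts data frame.
#' @param factors Optional tibble from [tmm_factors()] (columns `sample_id`,
#'   `lib_size`, `factor`), or `NULL` for raw library sizes.
#' @return Numeric matrix of CPM values with the input dimnames.
#' @export
compute_cpm <- function(counts, factors = NULL) {
  m <- as_count_matrix(counts)
  if (is.null(factors)) {
    eff <- colSums(m)
  } else {
    idx <- match(colnames(m), factors$sample_id)
    if (anyNA(idx)) abort("factors missing for some samples")
    eff <- factors$lib_size[idx] * factors$factor[idx]
  }
  zero <- eff == 0
  if (any(zero)) {
    abort(paste0("zero library size for sample(s): ",
                 paste(colnames(m)[zero], collapse = ", ")))
  }
  sweep(m, 2, eff, "/") * 1e6
}

#' Filter weakly expressed genes within a stage
#'
#' A gene is kept when it reaches `cpm1` CPM in at least `ceil(frac1 * n)` of
#' the stage's samples, or `cpm2` CPM in at least `ceil(frac2 * n)` samples.
#' With the defaults (1 CPM in half, 2 CPM in a quarter of 16 samples) the
#' second prong retains genes expressed in only the four replicates of a
#' single taxon.
#'
#' @param counts Count matrix or counts data frame, restricted to one stage.
#' @param cpm1,frac1 First prong: CPM threshold and sample fraction.
#' @param cpm2,frac2 Second prong.
#' @param factors Optional normalization factors passed to [compute_cpm()];
#'   filtering conventionally runs on raw-library CPM.
#' @return List with `counts` (the kept rows) and `keep` (named logical mask
#'   over the input genes).
#' @export
filter_low_expression <- function(counts, cpm1 = 1, frac1 = 0.5,
                                  cpm2 = 2, frac2 = 0.25, factors = NULL) {
  m <- as_count_matrix(counts)
  cpm <- compute_cpm(m, factors)
  n <- ncol(m)
  need1 <- ceiling(frac1 * n)
  need2 <- ceiling(frac2 * n)
  keep <- rowSums(cpm >= cpm1) >= need1 | rowSums(cpm >= cpm2) >= need2
  list(counts = m[keep, , drop = FALSE], keep = keep)
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes between-sample scaling factors by the TMM method: for each
#' sample, the weighted mean of gene-wise log2 expression ratios (M) against
#' a reference sample, after trimming the most extreme `trim_m` of M values
#' on each side and the most extreme `trim_a` of average log expression (A)
#' on each side; weights are inverse approximate binomial variances. The
#' reference is the sample whose 75th-percentile count fraction is closest
#' to the mean across samples. Factors are rescaled to geometric mean 1.
#'
#' Genes with a zero count in either the sample or the reference are
#' excluded from the trimmed mean. Library sizes default to column totals;
#' passing them explicitly makes the factors absorb pure depth changes.
#'
#' @param counts Count matrix or counts data frame (one stage).
#' @param trim_m,trim_a Two-sided trim fractions for M and A.
#' @param lib_sizes Optional named/numeric vector of library sizes.
#' @param ref_column Optional fixed reference sample (index); by default
#'   the 75th-percentile rule chooses it.
#' @return Tibble with columns `sample_id`, `lib_size`, `factor`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05,
                        lib_sizes = NULL, ref_column = NULL) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 2) abort("TMM needs at least 2 samples")
  lib <- lib_sizes %||% colSums(m)
  if (any(lib <= 0)) abort("every sample needs a positive library size")

  f75 <- vapply(seq_len(ncol(m)),
                function(j) quantile(m[, j], 0.75, names = FALSE) / lib[j],
                numeric(1))
  ref <- ref_column %||% which.min(abs(f75 - mean(f75)))

  f <- vapply(seq_len(ncol(m)), function(j) {
    tmm_pair_factor(m[, j], m[, ref], lib[j], lib[ref], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  tibble(sample_id = colnames(m), lib_size = unname(lib), factor = unname(f))
}

# One sample's unscaled TMM factor against the reference column.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  M <- log2(p_obs[keep] / p_ref[keep])
  A <- (log2(p_obs[keep]) + log2(p_ref[keep])) / 2
  w <- 1 / ((n_obs - obs[keep]) / (n_obs * obs[keep]) +
              (n_ref - ref[keep]) / (n_ref * ref[keep]))
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * trim_m) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1
  hiA <- n + 1 - loA
  rM <- rank(M)
  rA <- rank(A)
  sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(sel)) return(1)
  2^(sum(M[sel] * w[sel]) / sum(w[sel]))
}
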