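#' Estimate the common negative-binomial dispersion
#'
#' Maximizes, over a single dispersion value shared by all genes, the summed
#' profile log-likelihood of the negative-binomial model in which each gene
#' has one free mean per group (taxon) and offsets equal to log effective
#' library size. The group means are profiled out by Newton scoring at every
#' candidate dispersion, and the Cox-Reid adjustment (minus half the log
#' determinant of the mean-parameter information) corrects the downward
#' bias that plug-in mean estimates would otherwise induce.
#'
#' @param counts Count matrix or counts data frame (one stage).
#' @param groups Group labels (e.g. taxa), one per sample, in column order.
#' @param factors Normalization factors from [tmm_factors()].
#' @param interval Search interval for the dispersion.
#' @return The common dispersion (scalar).
#' @export
estimate_common_dispersion <- function(counts, groups, factors,
                                       interval = c(1e-6, 20)) {
  m <- as_count_matrix(counts)
  if (all(m == 0)) abort("all-zero count matrix")
  if (length(groups) != ncol(m)) abort("one group label per sample required")
  offsets <- nb_offsets(m, factors)
  obj <- function(log_phi) {
    sum(nb_group_loglik(m, offsets, groups, exp(log_phi), adjust = TRUE))
  }
  opt <- optimize(obj, log(interval), maximum = TRUE, tol = 1e-8)
  exp(opt$maximum)
}

#' Estimate shrunken per-gene dispersions
#'
#' Per-gene dispersions are the maximizers of a weighted objective
#' `loglik_g(phi) + prior_weight * anchor(phi)`, where `loglik_g` is the
#' Cox-Reid adjusted profile log-likelihood of gene g and `anchor(phi)` is
#' the per-observation common-dispersion log-likelihood: the average of
#' `loglik_g` across all genes, divided by the number of samples, so its
#' maximum is the common dispersion and `prior_weight` counts the
#' pseudo-observations supporting it. `prior_weight = 0` gives unshrunken
#' per-gene maximum-likelihood estimates; very large weights collapse
#' every gene onto the common dispersion.
#'
#' With `anchor = "trend"` the anchor is computed within abundance bins
#' (quantiles of average log CPM) instead of globally, so each gene shrinks
#' toward the typical dispersion of genes at its own expression level.
#' When the true dispersion falls with abundance — the usual shape in
#' RNA-seq — a single global anchor drags well-expressed genes' estimates
#' upward and visibly costs detection power, so the analysis wrappers
#' ([de_all_pairs()], [run_full()]) use the trend anchor.
#'
#' Maximization is over a fixed geometric grid of candidate dispersions
#' centered on (and containing) the common value, spanning `grid_span`
#' octaves either side with `grid_length` points; estimates are reported at
#' grid resolution.
#'
#' @param counts Count matrix or counts data frame (one stage).
#' @param groups Group labels, one per sample.
#' @param factors Normalization factors from [tmm_factors()].
#' @param common Common dispersion from [estimate_common_dispersion()].
#' @param prior_weight Strength of shrinkage toward the anchor.
#' @param grid_length,grid_span Grid resolution and half-width (octaves).
#' @param anchor `"common"` (global anchor, the default) or `"trend"`
#'   (abundance-binned anchor).
#' @param n_bins Number of abundance bins for the trend anchor.
#' @return List with elements `common` (scalar) and `tagwise` (tibble
#'   `gene_id`, `dispersion`).
#' @export
estimate_tagwise_dispersions <- function(counts, groups, factors, common,
                                         prior_weight = 10,
                                         grid_length = 65, grid_span = 8,
                                         anchor = c("common", "trend"),
                                         n_bins = 20) {
  anchor <- match.arg(anchor)
  m <- as_count_matrix(counts)
  offsets <- nb_offsets(m, factors)
  grid <- common * 2^seq(-grid_span, grid_span, length.out = grid_length)
  L <- vapply(grid,
              function(phi) nb_group_loglik(m, offsets, groups, phi,
                                            adjust = TRUE),
              numeric(nrow(m)))
  if (anchor == "trend" && nrow(m) >= 200) {
    acpm <- log2((rowSums(m) + 0.5) / sum(exp(offsets)) * 1e6)
    n_bins <- min(n_bins, floor(nrow(m) / 50))
    bin <- cut(rank(acpm, ties.method = "first"), breaks = n_bins,
               labels = FALSE)
    A <- matrix(0, nrow(m), ncol(L))
    for (b in unique(bin)) {
      A[bin == b, ] <- matrix(colMeans(L[bin == b, , drop = FALSE]),
                              sum(bin == b), ncol(L), byrow = TRUE)
    }
    A <- A / ncol(m)
  } else {
    A <- matrix(colMeans(L) / ncol(m), nrow(m), ncol(L), byrow = TRUE)
  }
  best <- max.col(L + prior_weight * A, ties.method = "first")
  list(common = common,
       tagwise = tibble(gene_id = rownames(m), dispersion = grid[best]))
}

#' Pairwise negative-binomial differential expression test
#'
#' Likelihood-ratio test, per gene, of equal means in two taxa against free
#' group means, with fixed (shrunken) gene-wise dispersions and log
#' effective library sizes as offsets. The statistic is referred to a
#' chi-square distribution with one degree of freedom.
#'
#' The reported log2 fold change (focal over reference) is computed from
#' prior-augmented normalized group means: a prior count (default 0.5,
#' scaled by each sample's relative effective library size) is added to the
#' group totals so fold changes stay finite when one group is all zero.
#' Swapping the two groups negates `logFC` and leaves `PValue` unchanged.
#'
#' @param counts Count matrix or counts data frame (one stage).
#' @param samples Sample sheet tibble with `sample_id` and `taxon`.
#' @param focal,other Taxon labels to contrast (focal is the numerator).
#' @param factors Normalization factors from [tmm_factors()].
#' @param dispersions Result of [estimate_tagwise_dispersions()], or a
#'   single dispersion value.
#' @param prior_count Prior count used for the fold-change computation.
#' @return Tibble with columns `gene_id`, `logFC`, `logCPM`, `PValue`,
#'   `FDR` (Benjamini-Hochberg within this comparison), plus `stage`,
#'   `focal`, `other` metadata columns.
#' @export
test_pairwise <- function(counts, samples, focal, other, factors,
                          dispersions, prior_count = 0.5) {
  m <- as_count_matrix(counts)
  for (tx in c(focal, other)) {
    if (!tx %in% samples$taxon) abort(paste0("unknown taxon '", tx, "'"))
  }
  colA <- samples$sample_id[samples$taxon == focal]
  colB <- samples$sample_id[samples$taxon == other]
  if (length(colA) < 2 || length(colB) < 2) {
    abort("both groups need at least 2 replicates")
  }
  if (is.list(dispersions)) {
    phi <- dispersions$tagwise$dispersion[
      match(rownames(m), dispersions$tagwise$gene_id)]
    if (anyNA(phi)) abort("dispersions missing for some genes")
  } else {
    phi <- rep_len(dispersions, nrow(m))
  }

  sub <- m[, c(colA, colB), drop = FALSE]
  offsets <- nb_offsets(sub, factors)
  grp <- rep(c("A", "B"), c(length(colA), length(colB)))

  ll_null <- nb_profile_loglik(sub, offsets, phi)$loglik
  ll_alt <- nb_group_loglik(sub, offsets, grp, phi)
  lrt <- pmax(2 * (ll_alt - ll_null), 0)
  pval <- pchisq(lrt, df = 1, lower.tail = FALSE)

  eff <- exp(offsets)
  prior <- prior_count * eff / mean(eff)
  inA <- grp == "A"
  mean_cpm <- function(idx) {
    1e6 * (rowSums(sub[, idx, drop = FALSE]) + sum(prior[idx])) /
      sum(eff[idx])
  }
  logfc <- log2(mean_cpm(inA)) - log2(mean_cpm(!inA))
  logcpm <- log2(1e6 * (rowSums(sub) + sum(prior)) / sum(eff))

  stage <- if ("stage" %in% names(samples)) {
    paste(unique(samples$stage[samples$sample_id %in% c(colA, colB)]),
          collapse = "+")
  } else NA_character_
  tibble(gene_id = rownames(m), logFC = unname(logfc),
         logCPM = unname(logcpm), PValue = unname(pval),
         FDR = adjust_fdr(pval), stage = stage, focal = focal, other = other)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment. Input values outside `[0, 1]`
#' are an error rather than being clamped.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Numeric vector of BH q-values.
#' @export
adjust_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Run all pairwise comparisons at one stage
#'
#' Convenience wrapper: TMM factors, dispersion estimation across all taxa,
#' and the likelihood-ratio test for every ordered pair requested.
#'
#' @param counts Count matrix (one stage, already filtered).
#' @param samples Sample sheet for the same stage.
#' @param pairs Data frame with columns `focal` and `other`; defaults to all
#'   unordered taxon pairs.
#' @param prior_weight Shrinkage weight for tagwise dispersions.
#' @return Tibble of stacked [test_pairwise()] results.
#' @export
de_all_pairs <- function(counts, samples, pairs = NULL, prior_weight = 10) {
  m <- as_count_matrix(counts)
  factors <- tmm_factors(m)
  taxa <- unique(samples$taxon)
  if (is.null(pairs)) {
    cmb <- utils::combn(taxa, 2)
    pairs <- tibble(focal = cmb[1, ], other = cmb[2, ])
  }
  groups <- samples$taxon[match(colnames(m), samples$sample_id)]
  common <- estimate_common_dispersion(m, groups, factors)
  disp <- estimate_tagwise_dispersions(m, groups, factors, common,
                                       prior_weight = prior_weight,
                                       anchor = "trend")
  purrr::pmap_dfr(pairs, function(focal, other) {
    test_pairwise(m, samples, focal, other, factors, disp)
  })
}
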