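#' Log2 transform of a CPM matrix
#'
#' `log2(cpm + prior)`; the prior (default 1) keeps zeros finite.
#'
#' @param cpm Non-negative numeric matrix.
#' @param prior Pseudo-expression added before the log.
#' @return Numeric matrix.
#' @export
log_transform <- function(cpm, prior = 1) {
  if (any(cpm < 0)) abort("CPM values must be non-negative")
  log2(cpm + prior)
}

#' Principal component analysis of expression samples
#'
#' Centers each gene (row) of a log-expression matrix and decomposes the
#' sample-space covariance by singular value decomposition. Variance
#' fractions are \eqn{\sigma_k^2 / \sum \sigma^2}. Each component's sign is
#' fixed so that its largest-magnitude gene loading is positive, making
#' loading-based rankings reproducible.
#'
#' @param logmat Gene-by-sample matrix of log expression.
#' @param n_components Number of components to retain (truncated to the
#'   matrix rank, with a warning).
#' @return A `pupdevo_pca` object: list with `scores` (samples x k),
#'   `loadings` (genes x k), `var_frac`, `center`, `n_components`.
#' @export
pca_samples <- function(logmat, n_components = 3) {
  if (ncol(logmat) < 2) abort("PCA needs at least 2 samples")
  center <- rowMeans(logmat)
  xc <- logmat - center
  sv <- svd(t(xc))  # samples x genes
  tol <- max(dim(xc)) * max(sv$d) * .Machine$double.eps
  rank <- sum(sv$d > tol)
  if (n_components > rank) {
    warn(sprintf("only %d non-degenerate component(s); truncating", rank))
    n_components <- rank
  }
  k <- seq_len(n_components)
  loadings <- sv$v[, k, drop = FALSE]
  scores <- sv$u[, k, drop = FALSE] %*% diag(sv$d[k], nrow = length(k))
  # sign convention: dominant loading positive
  for (j in k) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(loadings) <- list(rownames(logmat), paste0("PC", k))
  dimnames(scores) <- list(colnames(logmat), paste0("PC", k))
  structure(list(scores = scores, loadings = loadings,
                 var_frac = sv$d[k]^2 / sum(sv$d^2),
                 all_var_frac = sv$d[seq_len(rank)]^2 / sum(sv$d^2),
                 center = center, n_components = n_components,
                 rank = rank),
            class = "pupdevo_pca")
}

#' @export
print.pupdevo_pca <- function(x, ...) {
  cat(sprintf("PCA of %d samples x %d genes, %d component(s) retained\n",
              nrow(x$scores), length(x$center), x$n_components))
  cat("variance fractions:",
      paste(sprintf("%.3f", x$var_frac), collapse = " "), "\n")
  invisible(x)
}

#' Rank genes by principal component loading
#'
#' Returns the genes sorted by their signed loading on one component,
#' descending, with ties broken by gene identifier — the ranking used for
#' loading-based pre-ranked GSEA.
#'
#' @param model A [pca_samples()] fit.
#' @param component Component index (1-based).
#' @return Tibble `gene_id`, `score`, sorted descending.
#' @export
loading_ranks <- function(model, component = 1) {
  if (component < 1 || component > model$n_components) {
    abort(sprintf("component %d not retained (model has %d)",
                  component, model$n_components))
  }
  tibble(gene_id = rownames(model$loadings),
         score = model$loadings[, component]) %>%
    arrange(desc(.data$score), .data$gene_id)
}
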