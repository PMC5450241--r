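#' Tidy a PCA fit
#'
#' @param x A [pca_samples()] object.
#' @param matrix One of `"scores"`, `"loadings"`, `"eigenvalues"`.
#' @param ... Unused.
#' @return A tibble in long-friendly wide form: samples (or genes) by
#'   components, or component variance fractions.
#' @method tidy pupdevo_pca
#' @export
tidy.pupdevo_pca <- function(x, matrix = "scores", ...) {
  switch(matrix,
    scores = bind_cols(tibble(sample_id = rownames(x$scores)),
                       as_tibble(x$scores)),
    loadings = bind_cols(tibble(gene_id = rownames(x$loadings)),
                         as_tibble(x$loadings)),
    eigenvalues = tibble(component = seq_along(x$var_frac),
                         var_frac = x$var_frac,
                         cumulative = cumsum(x$var_frac)),
    abort("matrix must be 'scores', 'loadings' or 'eigenvalues'")
  )
}

#' @rdname tidy.pupdevo_pca
#' @method glance pupdevo_pca
#' @export
glance.pupdevo_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), n_genes = length(x$center),
         n_components = x$n_components, rank = x$rank,
         var_frac_retained = sum(x$var_frac))
}

#' Tidy an intersection set
#'
#' @param x An `intersection_set`.
#' @param ... Unused.
#' @return Tibble `gene_id`, `direction`, `mean_logFC`.
#' @method tidy intersection_set
#' @export
tidy.intersection_set <- function(x, ...) x$table

#' @rdname tidy.intersection_set
#' @method glance intersection_set
#' @export
glance.intersection_set <- function(x, ...) {
  tibble(focal = x$focal, stage = x$stage, n_over = length(x$over),
         n_under = length(x$under), fdr_max = x$fdr_max,
         lfc_min = x$lfc_min)
}
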