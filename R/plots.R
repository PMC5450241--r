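#' Plot sample scores of an expression PCA
#'
#' @param object A [pca_samples()] fit.
#' @param samples Optional sample sheet used to colour points by taxon and
#'   shape them by stage.
#' @param components Two component indices to display.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pupdevo_pca
#' @export
autoplot.pupdevo_pca <- function(object, samples = NULL,
                                 components = c(1, 2), ...) {
  sc <- tidy(object, "scores")
  xvar <- paste0("PC", components[1])
  yvar <- paste0("PC", components[2])
  if (!is.null(samples)) {
    sc <- left_join(sc, samples, by = "sample_id")
  }
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data[[xvar]], .data[[yvar]]))
  if (!is.null(samples)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$taxon), size = 3)
  } else {
    p <- p + ggplot2::geom_point(size = 3)
  }
  p + ggplot2::labs(
    x = sprintf("%s (%.1f%%)", xvar, 100 * object$var_frac[components[1]]),
    y = sprintf("%s (%.1f%%)", yvar, 100 * object$var_frac[components[2]])) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a pairwise comparison
#'
#' @param result A [test_pairwise()] tibble.
#' @param fdr_max,lfc_min Thresholds used to highlight called genes.
#' @return A ggplot.
#' @export
plot_volcano <- function(result, fdr_max = 0.1, lfc_min = 0.2) {
  d <- result %>%
    mutate(called = .data$FDR <= fdr_max & abs(.data$logFC) >= lfc_min)
  ggplot2::ggplot(d, ggplot2::aes(.data$logFC, -log10(.data$PValue),
                                  colour = .data$called)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = sprintf("FDR<=%g & |lfc|>=%g", fdr_max, lfc_min)) +
    ggplot2::theme_minimal()
}

#' Plot a GSEA running enrichment score
#'
#' @param ranked Ranked tibble (`gene_id`, `score`).
#' @param geneset Gene-set members.
#' @return A ggplot of the running sum with hit positions marked.
#' @export
plot_gsea_running <- function(ranked, geneset) {
  es <- gsea_es(ranked, geneset)
  ids <- if (is.data.frame(ranked)) ranked$gene_id else ranked
  d <- tibble(rank = seq_along(es$running), running = es$running,
              hit = ids %in% geneset)
  ggplot2::ggplot(d, ggplot2::aes(.data$rank, .data$running)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_rug(data = d[d$hit, ], sides = "b") +
    ggplot2::labs(y = "running enrichment score",
                  subtitle = sprintf("ES = %.3f", es$es)) +
    ggplot2::theme_minimal()
}

#' Histogram of interval lengths in a catalog
#'
#' @param catalog Interval catalog tibble.
#' @param binwidth Histogram bin width in bp.
#' @return A ggplot.
#' @export
plot_interval_lengths <- function(catalog, binwidth = 25) {
  d <- mutate(catalog, length = .data$end - .data$start)
  ggplot2::ggplot(d, ggplot2::aes(.data$length)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "interval length (bp)", y = "intervals") +
    ggplot2::theme_minimal()
}
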