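#' Build a focal-taxon intersection set
#'
#' Given the three pairwise comparisons of one focal taxon against each
#' other taxon at a stage, returns the genes differentially expressed in
#' all of them with a consistent direction: the over-list holds genes with
#' `FDR <= fdr_max` and `logFC >= lfc_min` (focal as numerator) in every
#' comparison, the under-list the analogue with `logFC <= -lfc_min`. Genes
#' whose fold-change signs disagree across comparisons are excluded.
#'
#' @param results List (or stacked tibble) of [test_pairwise()] results,
#'   all sharing the focal taxon, stage, and gene universe.
#' @param fdr_max Maximum FDR per comparison.
#' @param lfc_min Minimum |log2 fold change| per comparison.
#' @return An `intersection_set`: list with `focal`, `stage`, `over`,
#'   `under` (character vectors), `fdr_max`, `lfc_min`, and `table` (tibble
#'   `gene_id`, `direction`, `mean_logFC` over the comparisons).
#' @export
build_intersection_set <- function(results, fdr_max = 0.1, lfc_min = 0.2) {
  if (is.data.frame(results)) {
    results <- split(results, results$other)
  }
  if (length(results) < 2) abort("need the focal taxon's pairwise comparisons")
  universe <- results[[1]]$gene_id
  for (r in results[-1]) {
    if (!identical(sort(r$gene_id), sort(universe))) {
      diff <- c(setdiff(r$gene_id, universe), setdiff(universe, r$gene_id))
      abort(paste0("gene universes differ across comparisons: ",
                   paste(head(diff, 5), collapse = ", ")))
    }
  }
  focal <- unique(unlist(lapply(results, function(r) unique(r$focal))))
  stage <- unique(unlist(lapply(results, function(r) unique(r$stage))))
  if (length(focal) > 1) abort("comparisons disagree on the focal taxon")

  aligned <- lapply(results, function(r) r[match(universe, r$gene_id), ])
  sig <- Reduce(`&`, lapply(aligned, function(r) r$FDR <= fdr_max))
  over <- sig & Reduce(`&`, lapply(aligned, function(r) r$logFC >= lfc_min))
  under <- sig & Reduce(`&`, lapply(aligned, function(r) r$logFC <= -lfc_min))
  mean_lfc <- Reduce(`+`, lapply(aligned, function(r) r$logFC)) /
    length(aligned)

  tab <- bind_rows(
    tibble(gene_id = universe[over], direction = "over",
           mean_logFC = mean_lfc[over]),
    tibble(gene_id = universe[under], direction = "under",
           mean_logFC = mean_lfc[under])
  )
  structure(list(focal = focal, stage = stage,
                 over = universe[over], under = universe[under],
                 fdr_max = fdr_max, lfc_min = lfc_min, table = tab),
            class = "intersection_set")
}

#' @export
print.intersection_set <- function(x, ...) {
  cat(sprintf("Intersection set: %s at %s (FDR <= %g, |log2FC| >= %g)\n",
              x$focal, x$stage, x$fdr_max, x$lfc_min))
  cat(sprintf("  %d overexpressed, %d underexpressed\n",
              length(x$over), length(x$under)))
  invisible(x)
}

#' Genes shared between two focal-taxon intersection sets
#'
#' Finds genes present (in either direction) in both of two intersection
#' sets from the same stage — e.g. genes differentially expressed in both
#' trophic extremes — annotated with their direction in each set.
#'
#' @param setA,setB `intersection_set` objects for the same stage.
#' @return Tibble with `gene_id`, `direction_A`, `direction_B`.
#' @export
shared_extreme_genes <- function(setA, setB) {
  if (!identical(setA$stage, setB$stage)) {
    abort("intersection sets come from different stages")
  }
  dir_of <- function(s, g) {
    dplyr::case_when(g %in% s$over ~ "over", g %in% s$under ~ "under")
  }
  shared <- intersect(c(setA$over, setA$under), c(setB$over, setB$under))
  tibble(gene_id = sort(shared)) %>%
    mutate(direction_A = dir_of(setA, .data$gene_id),
           direction_B = dir_of(setB, .data$gene_id))
}

#' Classify multi-stage and constitutive differential expression
#'
#' Takes one focal taxon's intersection sets across all sampled stages and
#' reports (i) the union of their genes, (ii) the subset appearing in sets
#' at two or more stages with its percentage of the union, and (iii) the
#' constitutively differentially expressed subset: multi-stage genes whose
#' mean log2 fold change (over the three pairwise comparisons) has the same
#' sign at every stage, significance aside.
#'
#' @param sets List of `intersection_set` objects, one per stage.
#' @param stage_lfc Tibble with columns `gene_id`, `stage`, `mean_logFC`
#'   giving each gene's mean fold change at every stage (e.g. from
#'   [rank_by_mean_logfc()] inputs). Genes missing a value at some stage
#'   (filtered out there) cannot be called constitutive and are listed in
#'   `diagnostics`.
#' @return List with `focal`, `union`, `multi_stage`, `percent_multi`,
#'   `constitutive`, `diagnostics`, and per-gene `table`.
#' @export
classify_constitutive <- function(sets, stage_lfc) {
  focal <- unique(vapply(sets, function(s) s$focal, character(1)))
  if (length(focal) != 1) abort("sets must share one focal taxon")
  stages <- vapply(sets, function(s) s$stage, character(1))
  if (anyDuplicated(stages)) abort("one intersection set per stage expected")

  membership <- lapply(sets, function(s) c(s$over, s$under))
  union_genes <- sort(unique(unlist(membership)))
  n_stages_in <- vapply(union_genes, function(g) {
    sum(vapply(membership, function(m) g %in% m, logical(1)))
  }, integer(1))
  multi <- union_genes[n_stages_in >= 2]

  wide <- stage_lfc %>%
    filter(.data$gene_id %in% union_genes) %>%
    tidyr::pivot_wider(id_cols = "gene_id", names_from = "stage",
                       values_from = "mean_logFC")
  lfc_mat <- as.matrix(wide[setdiff(names(wide), "gene_id")])
  rownames(lfc_mat) <- wide$gene_id

  has_all <- function(g) {
    g %in% rownames(lfc_mat) &&
      all(stages %in% colnames(lfc_mat)) &&
      !anyNA(lfc_mat[g, stages])
  }
  same_sign <- function(g) {
    v <- lfc_mat[g, stages]
    all(v > 0) || all(v < 0)
  }
  complete <- vapply(multi, has_all, logical(1))
  constitutive <- multi[complete][vapply(multi[complete], same_sign,
                                         logical(1))]
  diagnostics <- multi[!complete]
  if (length(diagnostics) > 0) {
    inform(sprintf(
      "%d multi-stage gene(s) lack a fold change at some stage and cannot be assessed for constitutive expression",
      length(diagnostics)))
  }

  tab <- tibble(gene_id = union_genes, n_stages = n_stages_in,
                multi_stage = n_stages_in >= 2,
                constitutive = union_genes %in% constitutive)
  list(focal = focal, union = union_genes, multi_stage = multi,
       percent_multi = if (length(union_genes) > 0) {
         100 * length(multi) / length(union_genes)
       } else NA_real_,
       constitutive = constitutive, diagnostics = diagnostics, table = tab)
}
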