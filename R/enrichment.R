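#' Permutation test for curated-list overrepresentation
#'
#' Assesses whether a query gene list (e.g. an intersection set) contains
#' more members of a curated list (e.g. genes with known craniofacial or
#' bone phenotypes) than expected by chance: `n_perm` random sets of the
#' same size as the query are drawn from the universe without replacement
#' and scored for curated membership. The empirical p-value uses the
#' add-one correction `(1 + #{null >= observed}) / (1 + n_perm)`; the exact
#' hypergeometric upper tail is reported alongside as the analytic
#' counterpart.
#'
#' @param query Character vector of query genes (subset of `universe`).
#' @param curated Character vector of curated genes.
#' @param universe Character vector of all testable genes.
#' @param n_perm Number of random draws.
#' @param seed Integer seed.
#' @return List with `observed`, `null_counts`, `null_mean`, `p_empirical`,
#'   `p_hypergeometric`.
#' @export
permutation_overlap_test <- function(query, curated, universe,
                                     n_perm = 1000, seed = 1L) {
  query <- unique(query)
  curated <- unique(curated)
  universe <- unique(universe)
  if (length(query) > length(universe)) abort("query larger than universe")
  if (!all(query %in% universe)) abort("query must be a subset of the universe")
  set.seed(seed)
  in_curated <- universe %in% curated
  K <- sum(in_curated)
  observed <- sum(query %in% curated)
  null_counts <- vapply(seq_len(n_perm), function(i) {
    sum(in_curated[sample.int(length(universe), length(query))])
  }, integer(1))
  list(observed = observed, null_counts = null_counts,
       null_mean = mean(null_counts),
       p_empirical = (1 + sum(null_counts >= observed)) / (1 + n_perm),
       p_hypergeometric = hypergeometric_tail(observed, K, length(query),
                                              length(universe)))
}

#' Hypergeometric upper tail
#'
#' P(X >= k) when drawing `n` items from `N` of which `K` are marked.
#' Computed in log space via [stats::phyper()].
#'
#' @param k Observed overlap.
#' @param K Number of marked items in the population.
#' @param n Draw size.
#' @param N Population size.
#' @return Upper-tail probability.
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  if (k < 0 || n < 0 || K < 0 || n > N || K > N || k > n) {
    abort("inconsistent hypergeometric counts")
  }
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GSEA enrichment score, classic scheme
#'
#' Walks the ranked gene list accumulating `+1/G` at each gene-set member
#' ("hit", with `G` the number of members present in the list) and
#' `-1/(N-G)` at each non-member. The enrichment score is the value of the
#' running sum with the largest absolute deviation from zero (positive
#' preferred on an exact tie).
#'
#' @param ranked Tibble from [rank_by_mean_logfc()] or [loading_ranks()]
#'   (columns `gene_id`, `score`, already sorted), or a character vector of
#'   gene identifiers in rank order.
#' @param geneset Character vector of gene-set members; members absent from
#'   the ranked list are ignored.
#' @return List with `es` and `running` (the full running sum, length N).
#' @export
gsea_es <- function(ranked, geneset) {
  ids <- if (is.data.frame(ranked)) ranked$gene_id else as.character(ranked)
  hit <- ids %in% geneset
  G <- sum(hit)
  N <- length(ids)
  if (G == 0) abort("no gene-set member present in the ranked list")
  if (G == N) abort("gene set covers the entire ranked list (degenerate)")
  # running-sum values computed directly from integer hit/miss counts so
  # they are exact (no accumulated rounding): h/G - m/(N-G)
  h <- cumsum(hit)
  running <- h / G - (seq_len(N) - h) / (N - G)
  es <- running[which.max(abs(running))]
  # prefer the positive extreme when |max| == |min| exactly
  if (abs(max(running)) == abs(min(running)) && max(running) > 0) {
    es <- max(running)
  }
  list(es = es, running = running)
}

# Enrichment score from sorted hit positions: extremes of the running sum
# occur at hits (upper) and immediately before hits or at the end (lower).
es_from_positions <- function(pos, N, G) {
  pos <- sort(pos)
  k <- seq_len(G)
  at_hit <- k / G - (pos - k) / (N - G)
  before_hit <- (k - 1) / G - (pos - k) / (N - G)
  hi <- max(at_hit)
  lo <- min(before_hit, 0)
  if (hi >= -lo) hi else lo
}

#' Pre-ranked GSEA with gene-label permutations
#'
#' For every gene set in the collection, computes the classic enrichment
#' score of [gsea_es()] and builds its null distribution from random
#' same-size draws of positions in the ranked list (the standard null for
#' pre-ranked mode, where no sample-level phenotype permutation exists).
#' `NES = ES / mean(|null ES| of matching sign)`; the nominal p-value is
#' the add-one-corrected fraction of same-sign null scores at least as
#' extreme. The FDR q-value compares, within the matching-sign pool, the
#' fraction of all normalized null scores beyond a set's NES to the
#' fraction of observed NES beyond it, clipped at 1.
#'
#' Null draws are shared across sets of equal size. With
#' `exhaustive = TRUE` (small lists only) the null enumerates every
#' possible same-size subset and the nominal p is the exact tail fraction.
#'
#' @param ranked Ranked tibble (`gene_id`, `score`), descending.
#' @param collection Named list of character vectors, as from [read_gmt()].
#' @param n_perm Permutations per set size.
#' @param seed Integer seed.
#' @param min_size Sets with fewer members present are skipped.
#' @param exhaustive Enumerate all subsets instead of sampling.
#' @return Tibble with `name`, `size`, `es`, `nes`, `pval`, `fdr`,
#'   `leading_edge`.
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 1000, seed = 1L,
                           min_size = 1, exhaustive = FALSE) {
  ids <- ranked$gene_id
  N <- length(ids)
  set.seed(seed)
  present <- lapply(collection, function(s) which(ids %in% s))
  sizes <- lengths(present)
  usable <- sizes >= min_size & sizes < N
  dropped <- names(collection)[!usable]
  if (length(dropped) > 0) {
    warn(paste0("skipping degenerate/empty set(s): ",
                paste(dropped, collapse = ", ")))
  }
  present <- present[usable]
  if (length(present) == 0) abort("no usable gene set in the collection")

  null_for_size <- function(G) {
    if (exhaustive) {
      combs <- utils::combn(N, G)
      apply(combs, 2, es_from_positions, N = N, G = G)
    } else {
      vapply(seq_len(n_perm),
             function(i) es_from_positions(sample.int(N, G), N, G),
             numeric(1))
    }
  }
  nulls <- lapply(setNames(sort(unique(lengths(present))), NULL),
                  function(G) null_for_size(G))
  names(nulls) <- as.character(sort(unique(lengths(present))))

  per_set <- purrr::imap_dfr(present, function(pos, nm) {
    G <- length(pos)
    es <- es_from_positions(pos, N, G)
    null <- nulls[[as.character(G)]]
    same <- if (es >= 0) null[null >= 0] else null[null < 0]
    denom <- mean(abs(same))
    nes <- if (length(same) > 0 && denom > 0) es / denom else NA_real_
    extreme <- sum(abs(same) >= abs(es))
    pval <- if (exhaustive) {
      if (length(same) > 0) extreme / length(same) else 1
    } else {
      (1 + extreme) / (1 + length(same))
    }
    lead <- leading_edge_size(pos, N, G, es)
    tibble(name = nm, size = G, es = es, nes = nes, pval = pval,
           leading_edge = lead)
  })

  # normalized null pool for the FDR computation
  norm_null <- unlist(lapply(names(nulls), function(g) {
    null <- nulls[[g]]
    pos_mean <- mean(null[null >= 0])
    neg_mean <- mean(abs(null[null < 0]))
    ifelse(null >= 0, null / pos_mean, null / neg_mean)
  }), use.names = FALSE)
  obs_nes <- per_set$nes
  per_set$fdr <- vapply(seq_len(nrow(per_set)), function(i) {
    nes <- obs_nes[i]
    if (is.na(nes)) return(NA_real_)
    if (nes >= 0) {
      num <- mean(norm_null[norm_null >= 0] >= nes)
      den <- mean(obs_nes[!is.na(obs_nes) & obs_nes >= 0] >= nes)
    } else {
      num <- mean(norm_null[norm_null < 0] <= nes)
      den <- mean(obs_nes[!is.na(obs_nes) & obs_nes < 0] <= nes)
    }
    min(1, num / den)
  }, numeric(1))
  per_set[, c("name", "size", "es", "nes", "pval", "fdr", "leading_edge")]
}

# Number of genes up to (or after, for negative ES) the running-sum extreme.
leading_edge_size <- function(pos, N, G, es) {
  k <- seq_len(G)
  if (es >= 0) {
    at_hit <- k / G - (pos - k) / (N - G)
    sum(pos <= pos[which.max(at_hit)])
  } else {
    before_hit <- (k - 1) / G - (pos - k) / (N - G)
    sum(pos >= pos[which.min(before_hit)])
  }
}

#' Rank genes by mean log2 fold change toward a focal taxon
#'
#' Averages the signed log2 fold changes of the focal taxon's three
#' pairwise comparisons and sorts genes by the mean, descending. Ties are
#' broken by gene identifier (ascending) so the ranking is deterministic.
#'
#' @param results List or stacked tibble of [test_pairwise()] results
#'   sharing the focal taxon and gene universe.
#' @return Tibble `gene_id`, `score`, sorted descending.
#' @export
rank_by_mean_logfc <- function(results) {
  if (is.data.frame(results)) results <- split(results, results$other)
  universe <- results[[1]]$gene_id
  for (r in results[-1]) {
    if (!identical(sort(r$gene_id), sort(universe))) {
      abort("gene universes differ across comparisons")
    }
  }
  aligned <- lapply(results, function(r) r$logFC[match(universe, r$gene_id)])
  score <- Reduce(`+`, aligned) / length(aligned)
  tibble(gene_id = universe, score = score) %>%
    arrange(desc(.data$score), .data$gene_id)
}
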