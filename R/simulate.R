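#' Configuration for a synthetic developmental expression experiment
#'
#' Builds the parameter set for [simulate_experiment()]. Defaults emulate a
#' crossed design of four taxa sampled at four developmental stages with four
#' biological replicates each (one parental pair per replicate), sequenced to
#' 10-20 million counted reads per library. Gene baseline abundances are
#' log-normal on the counts-per-million (CPM) scale and gene-wise
#' negative-binomial dispersions follow the decreasing trend
#' \eqn{\phi_g = d_0 + d_1/\mu_g} with \eqn{\mu_g} the baseline CPM, so that
#' low-abundance genes are noisier than abundant ones.
#'
#' Differential expression is planted as focal-taxon-versus-rest shifts:
#' each affected gene is assigned to exactly one taxon and its mean is
#' multiplied by `2^effect_size_log2` (randomly signed) in that taxon only,
#' so the true pairwise log2 fold change of that taxon against every other
#' taxon equals the planted value. A `constitutive_fraction` of affected
#' genes carry the same signed shift at every stage; the remainder get an
#' independently signed shift per stage (re-signed if all stages happen to
#' agree, so the two classes stay distinct).
#'
#' @param n_taxa,n_stages,n_reps Design dimensions.
#' @param n_genes Number of genes.
#' @param baseline_log_mean,baseline_log_sd Natural-log mean and sd of the
#'   gene baseline expression distribution, in CPM units.
#' @param dispersion_intercept,dispersion_slope Parameters \eqn{d_0, d_1} of
#'   the dispersion trend \eqn{\phi_g = d_0 + d_1/\mu_g}.
#' @param lib_size_range Lower and upper bound of the uniform distribution
#'   library sizes are drawn from (total counted reads per sample).
#' @param de_fraction Fraction of genes planted differentially expressed for
#'   each focal taxon (at every stage).
#' @param effect_size_log2 Magnitude of the planted |log2 fold change|.
#' @param constitutive_fraction Fraction of planted genes whose effect keeps
#'   the same sign at all stages.
#' @param focal_taxa Taxa that receive planted effects; defaults to all.
#' @param seed Integer seed; identical configurations give byte-identical
#'   simulated experiments.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa = 4, n_stages = 4, n_reps = 4, n_genes = 10000,
                       baseline_log_mean = 3, baseline_log_sd = 1.5,
                       dispersion_intercept = 0.04, dispersion_slope = 0.5,
                       lib_size_range = c(10e6, 20e6),
                       de_fraction = 0.05, effect_size_log2 = 0.4,
                       constitutive_fraction = 0.2,
                       focal_taxa = NULL, seed = 1L) {
  cfg <- list(
    n_taxa = as.integer(n_taxa), n_stages = as.integer(n_stages),
    n_reps = as.integer(n_reps), n_genes = as.integer(n_genes),
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    dispersion_intercept = dispersion_intercept,
    dispersion_slope = dispersion_slope,
    lib_size_range = as.numeric(lib_size_range),
    de_fraction = de_fraction, effect_size_log2 = effect_size_log2,
    constitutive_fraction = constitutive_fraction,
    focal_taxa = focal_taxa, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_taxa < 1 || cfg$n_stages < 1 || cfg$n_reps < 2 || cfg$n_genes < 1) {
    abort("invalid design: need n_taxa >= 1, n_stages >= 1, n_reps >= 2, n_genes >= 1")
  }
  for (f in c("de_fraction", "constitutive_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste(f, "must be in [0, 1]"))
  }
  if (cfg$dispersion_intercept <= 0 || cfg$dispersion_slope < 0) {
    abort("dispersion trend must be positive")
  }
  if (length(cfg$lib_size_range) != 2 || any(cfg$lib_size_range <= 0) ||
      diff(cfg$lib_size_range) < 0) {
    abort("lib_size_range must be two positive ordered values")
  }
  if (cfg$baseline_log_sd < 0) abort("baseline_log_sd must be >= 0")
  invisible(cfg)
}

taxon_labels <- function(n) paste0("T", seq_len(n))
stage_labels <- function(n) paste0("S", seq_len(n))

#' Simulate a developmental expression experiment with planted truth
#'
#' Draws a gene-by-sample count matrix from the negative-binomial model
#' described in [sim_config()]: counts for gene g in sample s have mean
#' \eqn{\mu_g \cdot (N_s / 10^6) \cdot 2^{\lambda}} where \eqn{\mu_g} is the
#' baseline CPM, \eqn{N_s} the library size, and \eqn{\lambda} the planted
#' log2 fold change for that sample's taxon and stage (zero for unaffected
#' genes), with gene-wise dispersion \eqn{\phi_g}.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements
#'   * `counts`: integer gene-by-sample matrix,
#'   * `samples`: tibble (`sample_id`, `taxon`, `stage`, `replicate`,
#'     `pair_id`) — one parental pair per replicate within taxon,
#'   * `truth`: tibble (`gene_id`, `taxon`, `stage`, `is_de`, `log2fc`) of
#'     every planted effect,
#'   * `gene_truth`: per-gene tibble (`gene_id`, `de_taxon`, `constitutive`,
#'     `baseline_cpm`, `dispersion`).
#' @export
simulate_experiment <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_genes <- config$n_genes
  taxa <- taxon_labels(config$n_taxa)
  stages <- stage_labels(config$n_stages)
  focal <- config$focal_taxa %||% taxa
  if (!all(focal %in% taxa)) abort("focal_taxa must be among the design taxa")

  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  mu <- exp(rnorm(n_genes, config$baseline_log_mean, config$baseline_log_sd))
  # normalise baselines to one million so they are true CPM values and the
  # realised library size matches the nominal one
  mu <- mu / sum(mu) * 1e6
  phi <- config$dispersion_intercept + config$dispersion_slope / mu

  samples <- tidyr::expand_grid(taxon = taxa, stage = stages,
                                replicate = seq_len(config$n_reps)) %>%
    mutate(sample_id = paste(.data$taxon, .data$stage,
                             paste0("r", .data$replicate), sep = "_"),
           pair_id = paste0(.data$taxon, "_pair", .data$replicate)) %>%
    select("sample_id", "taxon", "stage", "replicate", "pair_id")
  lib_sizes <- runif(nrow(samples), config$lib_size_range[1],
                     config$lib_size_range[2])

  # Planted truth: disjoint DE gene blocks, one per focal taxon.
  n_de <- round(config$de_fraction * n_genes)
  if (n_de * length(focal) > n_genes) {
    abort("de_fraction too large for disjoint per-taxon DE gene blocks")
  }
  de_taxon <- rep(NA_character_, n_genes)
  lfc <- array(0, dim = c(n_genes, length(taxa), length(stages)),
               dimnames = list(gene_ids, taxa, stages))
  if (n_de > 0 && config$effect_size_log2 != 0) {
    pool <- sample.int(n_genes, n_de * length(focal))
    for (i in seq_along(focal)) {
      block <- pool[((i - 1) * n_de + 1):(i * n_de)]
      de_taxon[block] <- focal[i]
      consti <- runif(n_de) < config$constitutive_fraction
      base_sign <- sample(c(-1, 1), n_de, replace = TRUE)
      for (g in seq_len(n_de)) {
        if (consti[g]) {
          signs <- rep(base_sign[g], length(stages))
        } else {
          signs <- sample(c(-1, 1), length(stages), replace = TRUE)
          if (length(stages) > 1 && length(unique(signs)) == 1) {
            signs[sample.int(length(stages), 1)] <- -signs[1]
          }
        }
        lfc[block[g], focal[i], ] <- signs * config$effect_size_log2
      }
    }
  }

  counts <- matrix(0, n_genes, nrow(samples),
                   dimnames = list(gene_ids, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    shift <- 2^lfc[, samples$taxon[j], samples$stage[j]]
    mean_j <- mu * (lib_sizes[j] / 1e6) * shift
    counts[, j] <- rnbinom(n_genes, size = 1 / phi, mu = mean_j)
  }

  truth <- tidyr::expand_grid(gene_id = gene_ids, taxon = taxa,
                              stage = stages) %>%
    mutate(log2fc = lfc[cbind(.data$gene_id, .data$taxon, .data$stage)],
           is_de = .data$log2fc != 0) %>%
    select("gene_id", "taxon", "stage", "is_de", "log2fc")

  # A gene is constitutive when planted with the same sign at every stage.
  sign_mat <- apply(lfc, c(1, 2), function(v) {
    if (all(v > 0) || all(v < 0)) 1L else 0L
  })
  constitutive <- !is.na(de_taxon) &
    sign_mat[cbind(seq_len(n_genes), match(de_taxon, taxa))] == 1L

  gene_truth <- tibble(gene_id = gene_ids, de_taxon = de_taxon,
                       constitutive = constitutive, baseline_cpm = mu,
                       dispersion = phi)

  list(counts = counts, samples = samples, truth = truth,
       gene_truth = gene_truth)
}

#' Draw a synthetic curated gene list
#'
#' Builds a curated-list fixture (mimicking, e.g., a literature-derived set
#' of craniofacial/bone genes) by mixing genes that are truly differentially
#' expressed in the simulation with background genes.
#'
#' @param truth The `truth` tibble from [simulate_experiment()].
#' @param universe Character vector of candidate gene identifiers.
#' @param n_from_de Number of members drawn from the truly-DE pool.
#' @param n_background Number drawn from the never-DE pool.
#' @param seed Integer seed.
#' @return Character vector of `n_from_de + n_background` distinct genes.
#' @export
simulate_curated_list <- function(truth, universe, n_from_de, n_background,
                                  seed = 1L) {
  set.seed(seed)
  de_genes <- unique(truth$gene_id[truth$is_de])
  de_pool <- intersect(universe, de_genes)
  bg_pool <- setdiff(universe, de_genes)
  if (n_from_de > length(de_pool)) {
    abort(sprintf("DE pool exhausted: requested %d, available %d",
                  n_from_de, length(de_pool)))
  }
  if (n_background > length(bg_pool)) {
    abort(sprintf("background pool exhausted: requested %d, available %d",
                  n_background, length(bg_pool)))
  }
  out <- c(sample(de_pool, n_from_de), sample(bg_pool, n_background))
  sample(out)
}

#' Simulate a synthetic gene-set collection
#'
#' Generates named gene sets over a universe, optionally concentrating some
#' sets on truly differentially expressed genes so enrichment signal exists.
#'
#' @param universe Gene identifiers to draw from.
#' @param n_sets Number of sets.
#' @param size_range Min and max set size.
#' @param enriched_in Optional character vector of genes (e.g. truth-DE);
#'   every other set draws 60% of its members from it.
#' @param seed Integer seed.
#' @return Named list of character vectors.
#' @export
simulate_gene_sets <- function(universe, n_sets = 20, size_range = c(15, 100),
                               enriched_in = NULL, seed = 1L) {
  set.seed(seed)
  sets <- vector("list", n_sets)
  names(sets) <- sprintf("SET_%02d", seq_len(n_sets))
  for (i in seq_len(n_sets)) {
    size <- sample(seq(size_range[1], size_range[2]), 1)
    if (!is.null(enriched_in) && i %% 2 == 0 &&
        length(intersect(enriched_in, universe)) > 0) {
      n_sig <- min(round(0.6 * size), length(intersect(enriched_in, universe)))
      sets[[i]] <- unique(c(sample(intersect(enriched_in, universe), n_sig),
                            sample(universe, size - n_sig)))
    } else {
      sets[[i]] <- sample(universe, size)
    }
  }
  sets
}

#' Simulate coverage tracks and consensus sequences
#'
#' Fixture generator for the supermatrix-construction stage: per-sample
#' per-scaffold read depths with planted low-coverage gaps, and per-sample
#' consensus sequences carrying random substitutions relative to a shared
#' reference. The returned truth catalog lists the maximal runs of positions
#' where every sample reaches `min_depth`, computed by a per-base scan at
#' generation time.
#'
#' @param n_samples,n_scaffolds,scaffold_len Design dimensions.
#' @param mean_depth Poisson mean of the per-base read depth.
#' @param gap_rate Expected number of planted gaps per kilobase per sample.
#' @param min_depth Depth threshold used for the truth catalog.
#' @param sub_rate Per-base substitution rate of sample consensus sequences.
#' @param seed Integer seed.
#' @return List with `depths` (list of sample -> scaffold -> integer vector),
#'   `consensus` (list of sample -> scaffold -> character), `reference`
#'   (scaffold -> character), and `truth` (tibble `scaffold`, `start`, `end`,
#'   0-based half-open).
#' @export
simulate_coverage_experiment <- function(n_samples = 4, n_scaffolds = 3,
                                         scaffold_len = 2000, mean_depth = 30,
                                         gap_rate = 2, min_depth = 10,
                                         sub_rate = 0.005, seed = 1L) {
  if (n_samples < 1 || n_scaffolds < 1 || scaffold_len < 1) {
    abort("dimensions must be positive")
  }
  set.seed(seed)
  scaffolds <- sprintf("scf%02d", seq_len(n_scaffolds))
  sample_ids <- sprintf("smp%02d", seq_len(n_samples))
  bases <- c("A", "C", "G", "T")

  reference <- lapply(setNames(scaffolds, scaffolds), function(s) {
    paste(sample(bases, scaffold_len, replace = TRUE), collapse = "")
  })

  depths <- lapply(setNames(sample_ids, sample_ids), function(sm) {
    lapply(setNames(scaffolds, scaffolds), function(s) {
      d <- rpois(scaffold_len, mean_depth)
      n_gaps <- rpois(1, gap_rate * scaffold_len / 1000)
      if (n_gaps > 0) {
        for (k in seq_len(n_gaps)) {
          w <- sample(5:50, 1)
          st <- sample.int(max(scaffold_len - w, 1), 1)
          d[st:(st + w - 1)] <- rpois(w, 0.5)
        }
      }
      d
    })
  })

  consensus <- lapply(setNames(sample_ids, sample_ids), function(sm) {
    lapply(setNames(scaffolds, scaffolds), function(s) {
      seq <- strsplit(reference[[s]], "")[[1]]
      hits <- which(runif(scaffold_len) < sub_rate)
      for (i in hits) seq[i] <- sample(setdiff(bases, seq[i]), 1)
      paste(seq, collapse = "")
    })
  })

  truth <- purrr::map_dfr(scaffolds, function(s) {
    ok <- rep(TRUE, scaffold_len)
    for (sm in sample_ids) ok <- ok & depths[[sm]][[s]] >= min_depth
    runs_from_logical(ok, s)
  })

  list(depths = depths, consensus = consensus, reference = reference,
       truth = truth)
}

# Maximal TRUE runs of a logical vector as 0-based half-open intervals.
runs_from_logical <- function(ok, scaffold) {
  if (!any(ok)) {
    return(tibble(scaffold = character(), start = integer(), end = integer()))
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(scaffold = scaffold, start = starts[keep] - 1L, end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
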