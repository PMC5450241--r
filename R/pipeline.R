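#' Pipeline configuration
#'
#' Assembles the configuration driving [run_full()]. Either a simulation
#' recipe (`sim`) or paths to a counts TSV and sample sheet CSV must be
#' given. Thresholds default to the study conventions: differential
#' expression at FDR <= 0.1 and |log2FC| >= 0.2 in all three comparisons,
#' gene set enrichment reported at FDR <= 0.25, 1000 permutations.
#'
#' @param out_dir Output directory (created if absent).
#' @param sim A [sim_config()] used to generate the experiment, or `NULL`.
#' @param counts_path,samples_path Input files when `sim` is `NULL`.
#' @param focal_taxa Taxa whose intersection sets are built (default: the
#'   first two taxa found).
#' @param fdr_max,lfc_min,gsea_fdr,n_perm Analysis thresholds.
#' @param curated Either a character vector of curated genes or a list
#'   `list(n_from_de =, n_background =)` to simulate one.
#' @param gene_sets Named list of gene sets, a GMT path, or a list
#'   `list(n_sets =)` to simulate a collection.
#' @param n_components Principal components retained (and used for
#'   loading-rank GSEA).
#' @param intervals Optional list of [simulate_coverage_experiment()]
#'   arguments to exercise the supermatrix stage, or `NULL` to skip it.
#' @param seed Integer seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(),
                            counts_path = NULL, samples_path = NULL,
                            focal_taxa = NULL,
                            fdr_max = 0.1, lfc_min = 0.2, gsea_fdr = 0.25,
                            n_perm = 1000,
                            curated = list(n_from_de = 60, n_background = 240),
                            gene_sets = list(n_sets = 20),
                            n_components = 3,
                            intervals = NULL, seed = 1L) {
  if (is.null(sim) && (is.null(counts_path) || is.null(samples_path))) {
    abort("either `sim` or both input paths must be given")
  }
  if (fdr_max < 0 || fdr_max > 1 || gsea_fdr < 0 || gsea_fdr > 1 ||
      lfc_min < 0 || n_perm < 1) {
    abort("thresholds out of range")
  }
  structure(list(out_dir = out_dir, sim = sim, counts_path = counts_path,
                 samples_path = samples_path, focal_taxa = focal_taxa,
                 fdr_max = fdr_max, lfc_min = lfc_min, gsea_fdr = gsea_fdr,
                 n_perm = n_perm, curated = curated, gene_sets = gene_sets,
                 n_components = n_components, intervals = intervals,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Consistency checks on a counts matrix and sample sheet: duplicate
#' identifiers, samples present in only one of the two, non-integer or
#' negative counts (named by cell), and unannotated genes in an optional
#' flag table. Fatal findings carry level `"fatal"`, advisory ones
#' `"warning"`.
#'
#' @param counts Count matrix, counts data frame, or path to a counts TSV.
#' @param samples Sample sheet tibble or path to a CSV.
#' @param gene_flags Optional gene flag table (see
#'   [remove_excluded_genes()]).
#' @return Tibble of findings (`level`, `message`); zero rows when clean.
#' @export
validate_inputs <- function(counts, samples, gene_flags = NULL) {
  findings <- tibble(level = character(), message = character())
  note <- function(level, message) {
    findings <<- bind_rows(findings, tibble(level = level, message = message))
  }
  if (is.character(counts) && length(counts) == 1) {
    counts <- tryCatch(read_counts(counts), error = function(e) {
      note("fatal", paste("cannot parse counts:", conditionMessage(e)))
      NULL
    })
  }
  if (is.character(samples) && length(samples) == 1) {
    samples <- read_sample_sheet(samples)
  }
  if (is.null(counts)) return(findings)
  m <- tryCatch(as_count_matrix(counts), error = function(e) {
    note("fatal", conditionMessage(e))
    NULL
  })
  if (is.null(m)) return(findings)

  bad <- which(m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    note("fatal", sprintf("non-integer count %.3f at gene %s, sample %s",
                          m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]],
                          colnames(m)[bad[1, 2]]))
  }
  if (anyDuplicated(samples$sample_id)) {
    note("fatal", "duplicate sample_id in sample sheet")
  }
  miss_m <- setdiff(samples$sample_id, colnames(m))
  if (length(miss_m) > 0) {
    note("fatal", paste("sample(s) in sheet but not in matrix:",
                        paste(miss_m, collapse = ", ")))
  }
  miss_s <- setdiff(colnames(m), samples$sample_id)
  if (length(miss_s) > 0) {
    note("warning", paste("sample(s) in matrix but not in sheet:",
                          paste(miss_s, collapse = ", ")))
  }
  if (!is.null(gene_flags)) {
    unknown <- setdiff(gene_flags$gene_id, rownames(m))
    if (length(unknown) > 0) {
      note("warning", sprintf("%d flagged gene(s) not in matrix",
                              length(unknown)))
    }
  }
  findings
}

# Orient a stacked pairwise-result table so `focal` is the numerator of
# every comparison involving it.
orient_results <- function(results, focal) {
  inv <- results$other == focal
  results$logFC[inv] <- -results$logFC[inv]
  tmp <- results$other[inv]
  results$other[inv] <- results$focal[inv]
  results$focal[inv] <- tmp
  results[results$focal == focal, , drop = FALSE]
}

#' Run the full comparative-transcriptomics pipeline
#'
#' Executes, per developmental stage: expression filtering, TMM
#' normalization, dispersion estimation across all taxa, all pairwise
#' negative-binomial tests; then per focal taxon: intersection sets,
#' shared-extreme-gene reports, constitutive classification, curated-list
#' permutation tests, and pre-ranked GSEA on both mean-log2FC and
#' PC-loading rankings; optionally the coverage-interval/supermatrix
#' stage. All outputs are plain-text files under `config$out_dir`, and the
#' returned manifest records parameters, seeds, and an MD5 hash of every
#' file, so a rerun with the same configuration reproduces identical
#' hashes.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly written as `manifest.json`.
#' @export
run_full <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  t0 <- Sys.time()
  log_step <- function(stage, msg) {
    inform(sprintf("[%s +%.1fs] %s", stage,
                   as.numeric(difftime(Sys.time(), t0, units = "secs")), msg))
  }

  # ---- inputs ------------------------------------------------------------
  if (!is.null(config$sim)) {
    log_step("simulate", "generating synthetic experiment")
    sim <- simulate_experiment(config$sim)
    counts <- sim$counts
    samples <- sim$samples
    truth <- sim$truth
    write_counts(counts, out("counts.tsv"))
    write_sample_sheet(samples, out("samples.csv"))
    readr::write_tsv(truth, out("truth.tsv"))
  } else {
    counts <- read_counts(config$counts_path)
    samples <- read_sample_sheet(config$samples_path)
    truth <- NULL
  }
  findings <- validate_inputs(counts, samples)
  if (any(findings$level == "fatal")) {
    abort(paste("input validation failed at stage 'validate':",
                paste(findings$message[findings$level == "fatal"],
                      collapse = "; ")))
  }

  stages <- unique(samples$stage)
  taxa <- unique(samples$taxon)
  focal_taxa <- config$focal_taxa %||% taxa[seq_len(min(2, length(taxa)))]

  curated <- config$curated
  if (is.list(curated) && !is.null(truth)) {
    curated <- simulate_curated_list(truth, rownames(counts),
                                     curated$n_from_de, curated$n_background,
                                     seed = config$seed + 101L)
    writeLines(curated, out("curated_genes.txt"))
  }
  gene_sets <- config$gene_sets
  if (is.character(gene_sets) && length(gene_sets) == 1) {
    gene_sets <- read_gmt(gene_sets)
  } else if (!is.null(names(gene_sets)) && "n_sets" %in% names(gene_sets)) {
    de_genes <- if (!is.null(truth)) unique(truth$gene_id[truth$is_de]) else NULL
    gene_sets <- simulate_gene_sets(rownames(counts), gene_sets$n_sets,
                                    enriched_in = de_genes,
                                    seed = config$seed + 202L)
    write_gmt(gene_sets, out("gene_sets.gmt"))
  }

  # ---- per-stage DE ------------------------------------------------------
  de_results <- list()
  stage_lfc <- list()
  for (st in stages) {
    log_step("de", paste("stage", st))
    sub <- subset_stage(counts, samples, st)
    filt <- filter_low_expression(sub$counts)
    readr::write_tsv(tibble(gene_id = names(filt$keep), keep = filt$keep),
                     out(paste0("filter_", st, ".tsv")))
    factors <- tmm_factors(filt$counts)
    readr::write_tsv(factors, out(paste0("tmm_", st, ".tsv")))
    groups <- sub$samples$taxon[match(colnames(filt$counts),
                                      sub$samples$sample_id)]
    common <- estimate_common_dispersion(filt$counts, groups, factors)
    disp <- estimate_tagwise_dispersions(filt$counts, groups, factors,
                                         common, anchor = "trend")
    cmb <- utils::combn(taxa, 2)
    res <- purrr::map_dfr(seq_len(ncol(cmb)), function(i) {
      test_pairwise(filt$counts, sub$samples, cmb[1, i], cmb[2, i],
                    factors, disp)
    })
    de_results[[st]] <- res
    for (i in seq_len(ncol(cmb))) {
      r <- res[res$focal == cmb[1, i] & res$other == cmb[2, i], ]
      write_de_table(r, out(paste0("de_", st, "_", cmb[1, i], "_vs_",
                                   cmb[2, i], ".tsv")))
    }
  }

  # ---- discovery, enrichment, ordination --------------------------------
  sets <- list()
  gsea_tables <- list()
  enrich_rows <- list()
  for (ft in focal_taxa) {
    sets[[ft]] <- list()
    for (st in stages) {
      oriented <- orient_results(de_results[[st]], ft)
      iset <- build_intersection_set(oriented, config$fdr_max,
                                     config$lfc_min)
      sets[[ft]][[st]] <- iset
      readr::write_tsv(iset$table[, c("gene_id", "direction")],
                       out(paste0("intersection_", ft, "_", st, ".tsv")))
      universe <- unique(oriented$gene_id)
      query <- c(iset$over, iset$under)
      if (length(query) > 0 && is.character(curated)) {
        pt <- permutation_overlap_test(query, curated, universe,
                                       n_perm = config$n_perm,
                                       seed = config$seed + 303L)
        enrich_rows[[paste(ft, st)]] <- tibble(
          focal = ft, stage = st, set_size = length(query),
          observed = pt$observed, null_mean = pt$null_mean,
          p_empirical = pt$p_empirical,
          p_hypergeometric = pt$p_hypergeometric)
      }
      ranked <- rank_by_mean_logfc(oriented)
      write_rnk(ranked, out(paste0("rank_logfc_", ft, "_", st, ".rnk")))
      gt <- gsea_preranked(ranked, gene_sets, n_perm = config$n_perm,
                           seed = config$seed + 404L)
      gt$ranking <- paste0("logFC_", ft)
      gt$stage <- st
      gsea_tables[[paste(ft, st)]] <- gt
      stage_lfc[[paste(ft, st)]] <- ranked %>%
        mutate(stage = st, focal = ft) %>%
        rename(mean_logFC = "score")
    }
    report <- classify_constitutive(sets[[ft]],
                                    bind_rows(stage_lfc[grepl(paste0("^", ft, " "),
                                                              names(stage_lfc))]))
    jsonlite::write_json(
      list(focal = ft, n_union = length(report$union),
           n_multi_stage = length(report$multi_stage),
           percent_multi = report$percent_multi,
           n_constitutive = length(report$constitutive),
           constitutive = report$constitutive),
      out(paste0("constitutive_", ft, ".json")), auto_unbox = TRUE,
      digits = NA)
  }
  if (length(focal_taxa) >= 2) {
    shared <- purrr::map_dfr(stages, function(st) {
      sh <- shared_extreme_genes(sets[[focal_taxa[1]]][[st]],
                                 sets[[focal_taxa[2]]][[st]])
      if (nrow(sh) > 0) sh$stage <- st
      sh
    })
    readr::write_tsv(shared, out("shared_extreme_genes.tsv"))
  }
  if (length(enrich_rows) > 0) {
    readr::write_tsv(bind_rows(enrich_rows), out("curated_enrichment.tsv"))
  }

  for (st in stages) {
    log_step("pca", paste("stage", st))
    sub <- subset_stage(counts, samples, st)
    filt <- filter_low_expression(sub$counts)
    factors <- tmm_factors(filt$counts)
    lcpm <- log_transform(compute_cpm(filt$counts, factors))
    pca <- pca_samples(lcpm, config$n_components)
    readr::write_tsv(tidy(pca, "scores"), out(paste0("pca_scores_", st, ".tsv")))
    readr::write_tsv(tidy(pca, "eigenvalues"),
                     out(paste0("pca_varfrac_", st, ".tsv")))
    for (k in seq_len(pca$n_components)) {
      ranked <- loading_ranks(pca, k)
      write_rnk(ranked, out(paste0("rank_pc", k, "_", st, ".rnk")))
      gt <- gsea_preranked(ranked, gene_sets, n_perm = config$n_perm,
                           seed = config$seed + 404L)
      gt$ranking <- paste0("PC", k)
      gt$stage <- st
      gsea_tables[[paste0("pc", k, st)]] <- gt
    }
  }
  gsea_all <- bind_rows(gsea_tables)
  readr::write_tsv(gsea_all, out("gsea_results.tsv"))
  readr::write_tsv(gsea_all[!is.na(gsea_all$fdr) &
                              gsea_all$fdr <= config$gsea_fdr, ],
                   out("gsea_significant.tsv"))

  # ---- optional supermatrix stage ---------------------------------------
  if (!is.null(config$intervals)) {
    log_step("intervals", "coverage-filtered supermatrix")
    cov <- do.call(simulate_coverage_experiment,
                   c(config$intervals, list(seed = config$seed + 505L)))
    catalog <- joint_covered_regions(cov$depths, min_depth = 10) %>%
      filter_by_length()
    sm <- build_supermatrix(cov$consensus, catalog)
    write_supermatrix(sm$alignment, out("supermatrix.fasta"))
    write_interval_bed(sm$map, out("supermatrix_map.bed"))
    cs <- catalog_summary(catalog)
    readr::write_tsv(cs$histogram, out("interval_lengths.tsv"))
  }

  # ---- manifest ----------------------------------------------------------
  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  hashes <- unname(tools::md5sum(file.path(config$out_dir, files)))
  manifest <- list(
    parameters = list(fdr_max = config$fdr_max, lfc_min = config$lfc_min,
                      gsea_fdr = config$gsea_fdr, n_perm = config$n_perm,
                      seed = config$seed,
                      focal_taxa = focal_taxa, stages = stages),
    outputs = as.list(setNames(hashes, files)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_step("done", sprintf("%d output files", length(files)))
  invisible(manifest)
}
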