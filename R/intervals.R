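# Coverage-filtered interval extraction and supermatrix construction.
#
# Coverage tracks are per-sample lists: track[[scaffold]] is an integer
# vector of per-base read depths. Coordinates are 0-based half-open
# internally and in bedGraph; FASTA output is plain sequence.

#' Jointly covered regions across all samples
#'
#' Finds the maximal runs of positions at which every sample reaches the
#' minimum read depth — the regions retained for phylogenetic analysis so
#' that the supermatrix contains no missing data.
#'
#' @param tracks Named list of coverage tracks, one per sample; each track
#'   is a named list of per-base depth vectors, one per scaffold.
#' @param min_depth Minimum depth required in every sample.
#' @return Interval catalog tibble: `scaffold`, `start`, `end` (0-based,
#'   half-open), `length`, sorted by scaffold then start.
#' @export
joint_covered_regions <- function(tracks, min_depth = 10) {
  if (length(tracks) == 0) abort("no coverage tracks supplied")
  scaffolds <- names(tracks[[1]])
  for (sm in names(tracks)) {
    if (!setequal(names(tracks[[sm]]), scaffolds)) {
      abort("samples disagree on the scaffold set")
    }
  }
  catalog <- purrr::map_dfr(sort(scaffolds), function(s) {
    lens <- vapply(tracks, function(t) length(t[[s]]), integer(1))
    if (length(unique(lens)) != 1) {
      abort(paste0("scaffold length mismatch across samples for '", s, "'"))
    }
    ok <- rep(TRUE, lens[1])
    for (sm in names(tracks)) ok <- ok & tracks[[sm]][[s]] >= min_depth
    runs_from_logical(ok, s)
  })
  catalog %>% mutate(length = .data$end - .data$start) %>%
    arrange(.data$scaffold, .data$start)
}

#' Filter an interval catalog by length
#'
#' Keeps intervals whose length lies in `[min_len, max_len]`. The defaults
#' encode the strict reading of the 50 bp to 1 kb rule: strictly longer
#' than 50 bases and strictly shorter than 1000.
#'
#' @param catalog Interval catalog tibble.
#' @param min_len,max_len Inclusive length bounds.
#' @return Filtered catalog, original order preserved.
#' @export
filter_by_length <- function(catalog, min_len = 51, max_len = 999) {
  if (min_len > max_len) abort("min_len must not exceed max_len")
  len <- catalog$end - catalog$start
  catalog[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Concatenate cataloged intervals into a supermatrix
#'
#' Extracts each cataloged interval from every sample's consensus sequence
#' and concatenates them in catalog order, yielding an alignment in which
#' all rows have length equal to the summed interval lengths. A coordinate
#' map records where each interval landed in the supermatrix. Intervals in
#' which any sample carries an `N` are reported; with `strict = TRUE` they
#' are dropped from the alignment.
#'
#' @param consensus Named list: `consensus[[sample]][[scaffold]]` is the
#'   scaffold-length sequence string for that sample.
#' @param catalog Interval catalog tibble (0-based half-open).
#' @param strict Drop intervals containing `N` in any sample.
#' @return List with `alignment` (named character vector), `map` (tibble
#'   `scaffold`, `start`, `end`, `sm_start`, `sm_end`, 0-based half-open in
#'   both coordinate systems) and `n_intervals` (tibble of intervals that
#'   contained `N`).
#' @export
build_supermatrix <- function(consensus, catalog, strict = FALSE) {
  sample_ids <- names(consensus)
  for (sm in sample_ids) {
    missing <- setdiff(unique(catalog$scaffold), names(consensus[[sm]]))
    if (length(missing) > 0) {
      abort(paste0("missing consensus for sample '", sm, "', scaffold '",
                   missing[1], "'"))
    }
  }
  if (nrow(catalog) == 0) {
    return(list(alignment = setNames(rep("", length(sample_ids)), sample_ids),
                map = tibble(scaffold = character(), start = integer(),
                             end = integer(), sm_start = integer(),
                             sm_end = integer()),
                n_intervals = catalog))
  }

  pieces <- lapply(sample_ids, function(sm) {
    vapply(seq_len(nrow(catalog)), function(i) {
      substr(consensus[[sm]][[catalog$scaffold[i]]],
             catalog$start[i] + 1, catalog$end[i])
    }, character(1))
  })
  names(pieces) <- sample_ids

  has_n <- Reduce(`|`, lapply(pieces, function(p) grepl("N", p, fixed = TRUE)))
  n_intervals <- catalog[has_n, , drop = FALSE]
  if (any(has_n)) {
    inform(sprintf("%d interval(s) contain N in at least one sample%s",
                   sum(has_n), if (strict) " (dropped)" else ""))
  }
  keep <- if (strict) !has_n else rep(TRUE, nrow(catalog))
  kept <- catalog[keep, , drop = FALSE]
  lens <- kept$end - kept$start
  sm_end <- cumsum(lens)
  map <- tibble(scaffold = kept$scaffold, start = kept$start,
                end = kept$end, sm_start = c(0L, head(sm_end, -1)),
                sm_end = sm_end)
  alignment <- vapply(sample_ids, function(sm) {
    paste(pieces[[sm]][keep], collapse = "")
  }, character(1))
  list(alignment = alignment, map = map, n_intervals = n_intervals)
}

# ---- bedGraph / FASTA interchange -----------------------------------------

#' Write / read one sample's coverage as bedGraph
#'
#' Four columns, 0-based half-open, run-length encoded, zero-depth runs
#' included so every base of every scaffold is represented and round-trips
#' exactly.
#'
#' @param track Named list of per-base depth vectors (one per scaffold).
#' @param path bedGraph file.
#' @export
write_coverage_bedgraph <- function(track, path) {
  runs <- lapply(sort(names(track)), function(s) {
    r <- rle(track[[s]])
    ends <- cumsum(r$lengths)
    list(scaffold = rep(s, length(ends)), start = ends - r$lengths + 1L,
         end = ends, score = r$values)
  })
  gr <- GenomicRanges::GRanges(
    unlist(lapply(runs, `[[`, "scaffold")),
    IRanges::IRanges(start = unlist(lapply(runs, `[[`, "start")),
                     end = unlist(lapply(runs, `[[`, "end"))),
    score = unlist(lapply(runs, `[[`, "score")))
  rtracklayer::export(gr, path, format = "bedGraph")
}

#' @rdname write_coverage_bedgraph
#' @export
read_coverage_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  track <- list()
  for (s in as.character(unique(GenomicRanges::seqnames(gr)))) {
    sub <- gr[GenomicRanges::seqnames(gr) == s]
    len <- max(GenomicRanges::end(sub))
    d <- integer(len)
    st <- GenomicRanges::start(sub)
    en <- GenomicRanges::end(sub)
    sc <- sub$score
    for (i in seq_along(sub)) d[st[i]:en[i]] <- sc[i]
    track[[s]] <- d
  }
  track
}

#' Write / read consensus sequences as FASTA
#'
#' One record per sample per scaffold, identifier `sample|scaffold`.
#'
#' @param consensus Nested list `consensus[[sample]][[scaffold]]`.
#' @param path FASTA file.
#' @export
write_consensus_fasta <- function(consensus, path) {
  seqs <- character(0)
  for (sm in names(consensus)) {
    for (s in names(consensus[[sm]])) {
      seqs[paste0(sm, "|", s)] <- consensus[[sm]][[s]]
    }
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 80)
}

#' @rdname write_consensus_fasta
#' @export
read_consensus_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- strsplit(names(ss), "|", fixed = TRUE)
  consensus <- list()
  for (i in seq_along(ss)) {
    consensus[[ids[[i]][1]]][[ids[[i]][2]]] <- as.character(ss[[i]])
  }
  consensus
}

#' Write a supermatrix alignment
#'
#' FASTA via Biostrings, or relaxed PHYLIP (name, space, full sequence on
#' one line).
#'
#' @param alignment Named character vector of equal-length sequences.
#' @param path Output file.
#' @param format `"fasta"` or `"phylip"`.
#' @export
write_supermatrix <- function(alignment, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(alignment), path,
                                width = 80)
  } else {
    lines <- c(paste(length(alignment), nchar(alignment[1])),
               paste(names(alignment), alignment))
    writeLines(lines, path)
  }
}

#' Read a supermatrix written by [write_supermatrix()]
#'
#' @param path FASTA file.
#' @return Named character vector.
#' @export
read_supermatrix <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Write an interval coordinate map as BED
#'
#' @param map Coordinate-map tibble from [build_supermatrix()] (or any
#'   catalog with `scaffold`, `start`, `end`).
#' @param path BED file (0-based half-open, as native to the format).
#' @export
write_interval_bed <- function(map, path) {
  if (nrow(map) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(map$scaffold,
                               IRanges::IRanges(start = map$start + 1L,
                                                end = map$end))
  if ("sm_start" %in% names(map)) {
    names(gr) <- paste0("sm:", map$sm_start, "-", map$sm_end)
  }
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Summarise an interval catalog
#'
#' @param catalog Interval catalog tibble.
#' @param breaks Histogram breaks for the length distribution.
#' @return List with `n`, `total_bp`, and a `histogram` tibble.
#' @export
catalog_summary <- function(catalog, breaks = c(0, 50, 100, 250, 500, 1000,
                                                Inf)) {
  len <- catalog$end - catalog$start
  h <- table(cut(len, breaks = breaks, right = FALSE))
  list(n = nrow(catalog), total_bp = sum(len),
       histogram = tibble(bin = names(h), count = as.integer(h)))
}
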