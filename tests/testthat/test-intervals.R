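test_that("joint coverage handles degenerate tracks", {
  tracks <- list(a = list(s1 = rep(20, 500)), b = list(s1 = rep(0, 500)))
  expect_equal(nrow(joint_covered_regions(tracks)), 0)

  full <- list(a = list(s1 = rep(12, 500)), b = list(s1 = rep(10, 500)))
  cat1 <- joint_covered_regions(full)
  expect_equal(as.data.frame(cat1[, 1:3]),
               data.frame(scaffold = "s1", start = 0L, end = 500L))

  bad <- list(a = list(s1 = rep(12, 500)), b = list(s1 = rep(12, 400)))
  expect_error(joint_covered_regions(bad), "length mismatch")
  expect_error(joint_covered_regions(list(a = list(s1 = 1:5),
                                          b = list(s2 = 1:5))),
               "scaffold set")
})

test_that("joint coverage equals the per-base boolean-AND oracle", {
  set.seed(14)
  for (trial in 1:25) {
    tracks <- lapply(setNames(1:3, paste0("smp", 1:3)), function(i) {
      lapply(setNames(1:2, c("sA", "sB")), function(s) {
        rpois(120, sample(c(5, 10, 15), 1))
      })
    })
    got <- joint_covered_regions(tracks, min_depth = 10)
    oracle <- oracle_joint_regions(tracks, 10)
    expect_equal(as.data.frame(got[, c("scaffold", "start", "end")]), oracle,
                 ignore_attr = TRUE)
  }
})

test_that("a single sub-threshold base splits exactly one interval", {
  tracks <- list(a = list(s1 = rep(20, 300)), b = list(s1 = rep(20, 300)))
  base <- joint_covered_regions(tracks)
  expect_equal(nrow(base), 1)
  tracks$a$s1[150] <- 3  # 0-based position 149
  split <- joint_covered_regions(tracks)
  expect_equal(nrow(split), 2)
  expect_equal(split$start, c(0L, 150L))
  expect_equal(split$end, c(149L, 300L))
})

test_that("length filter applies strict 50 bp / 1 kb bounds", {
  catalog <- tibble::tibble(
    scaffold = "s1",
    start = c(0L, 100L, 1200L, 2500L),
    end = c(50L, 199L, 2199L, 3500L))  # lengths 50, 99, 999, 1000
  kept <- filter_by_length(catalog)
  expect_equal(kept$start, c(100L, 1200L))
  expect_error(filter_by_length(catalog, min_len = 10, max_len = 5), "exceed")

  set.seed(15)
  rnd <- tibble::tibble(scaffold = "s1", start = 0L,
                        end = sample(1:2000, 50))
  expect_identical(filter_by_length(rnd),
                   rnd[(rnd$end - rnd$start) >= 51 &
                         (rnd$end - rnd$start) <= 999, ])
})

test_that("supermatrix slices, concatenates, and reports N content", {
  cons <- list(
    a = list(s1 = paste(rep("A", 30), collapse = ""),
             s2 = paste(rep("C", 30), collapse = "")),
    b = list(s1 = paste(rep("G", 30), collapse = ""),
             s2 = paste(rep("T", 30), collapse = "")))
  catalog <- tibble::tibble(scaffold = c("s1", "s2"),
                            start = c(10L, 0L), end = c(20L, 5L))
  sm <- build_supermatrix(cons, catalog)
  expect_equal(unname(nchar(sm$alignment)), c(15, 15))
  expect_equal(sm$alignment[["a"]], paste0(strrep("A", 10), strrep("C", 5)))
  expect_equal(sm$alignment[["b"]], paste0(strrep("G", 10), strrep("T", 5)))
  expect_equal(sm$map$sm_start, c(0L, 10L))
  expect_equal(sm$map$sm_end, c(10L, 15L))

  empty <- build_supermatrix(cons, catalog[0, ])
  expect_equal(unname(nchar(empty$alignment)), c(0, 0))
  expect_named(empty$alignment, c("a", "b"))

  # N handling: reported, dropped only in strict mode
  cons$a$s1 <- paste0(strrep("A", 12), "N", strrep("A", 17))
  expect_message(sm2 <- build_supermatrix(cons, catalog), "contain N")
  expect_equal(nrow(sm2$n_intervals), 1)
  expect_equal(unname(nchar(sm2$alignment)), c(15, 15))
  expect_message(sm3 <- build_supermatrix(cons, catalog, strict = TRUE),
                 "dropped")
  expect_equal(unname(nchar(sm3$alignment)), c(5, 5))

  expect_error(build_supermatrix(list(a = cons$a), catalog[1, ]),
               regexp = NA)
  expect_error(build_supermatrix(list(a = list(s2 = "ACGT")), catalog),
               "missing consensus")
})

test_that("supermatrix length equals the catalog total on random fixtures", {
  cov <- simulate_coverage_experiment(n_samples = 3, n_scaffolds = 2,
                                      scaffold_len = 800, mean_depth = 25,
                                      seed = 16)
  catalog <- filter_by_length(joint_covered_regions(cov$depths), 20, 500)
  sm <- build_supermatrix(cov$consensus, catalog)
  expect_true(all(nchar(sm$alignment) == sum(catalog$end - catalog$start)))
  # content equals a direct substring oracle
  for (sm_id in names(cov$consensus)) {
    oracle <- paste(vapply(seq_len(nrow(catalog)), function(i) {
      substr(cov$consensus[[sm_id]][[catalog$scaffold[i]]],
             catalog$start[i] + 1, catalog$end[i])
    }, character(1)), collapse = "")
    expect_identical(sm$alignment[[sm_id]], oracle)
  }
})

test_that("coverage, consensus, and supermatrix files round-trip", {
  cov <- simulate_coverage_experiment(n_samples = 2, n_scaffolds = 2,
                                      scaffold_len = 300, mean_depth = 20,
                                      seed = 17)
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  write_coverage_bedgraph(cov$depths$smp01, bg)
  back <- read_coverage_bedgraph(bg)
  expect_equal(back[sort(names(cov$depths$smp01))],
               cov$depths$smp01[sort(names(cov$depths$smp01))])

  fa <- withr::local_tempfile(fileext = ".fasta")
  write_consensus_fasta(cov$consensus, fa)
  expect_equal(read_consensus_fasta(fa), cov$consensus)

  catalog <- joint_covered_regions(cov$depths)
  smx <- build_supermatrix(cov$consensus, catalog)
  out <- withr::local_tempfile(fileext = ".fasta")
  write_supermatrix(smx$alignment, out)
  expect_equal(read_supermatrix(out), smx$alignment)
  phy <- withr::local_tempfile(fileext = ".phy")
  write_supermatrix(smx$alignment, phy, format = "phylip")
  lines <- readLines(phy)
  expect_equal(lines[1],
               paste(length(smx$alignment), nchar(smx$alignment[1])))

  bed <- withr::local_tempfile(fileext = ".bed")
  write_interval_bed(smx$map, bed)
  reread <- read.table(bed, sep = "\t")
  expect_equal(reread$V2, smx$map$start)  # BED is 0-based half-open
  expect_equal(reread$V3, smx$map$end)

  cs <- catalog_summary(catalog)
  expect_equal(cs$n, nrow(catalog))
  expect_equal(cs$total_bp, sum(catalog$end - catalog$start))
})
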