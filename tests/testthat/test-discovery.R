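fake_result <- function(gene_ids, logfc, fdr, focal = "T1", other = "T2",
                        stage = "S1") {
  tibble::tibble(gene_id = gene_ids, logFC = logfc,
                 logCPM = 5, PValue = fdr, FDR = fdr,
                 stage = stage, focal = focal, other = other)
}

test_that("intersection requires all three comparisons with one sign", {
  g <- c("a", "b", "c", "d")
  r1 <- fake_result(g, c(0.5, 0.5, 0.5, -0.5), c(0.01, 0.01, 0.01, 0.01),
                    other = "T2")
  r2 <- fake_result(g, c(0.5, 0.5, 0.5, -0.5), c(0.01, 0.5, 0.01, 0.01),
                    other = "T3")
  r3 <- fake_result(g, c(0.5, 0.5, -0.5, -0.5), c(0.01, 0.01, 0.01, 0.01),
                    other = "T4")
  set <- build_intersection_set(list(r1, r2, r3))
  expect_equal(set$over, "a")        # b fails FDR in one, c flips sign
  expect_equal(set$under, "d")
  expect_equal(glance(set)$n_over, 1)

  expect_error(
    build_intersection_set(list(r1, r2, fake_result(c("a", "b", "c", "e"),
                                                    rep(1, 4), rep(0.01, 4),
                                                    other = "T4"))),
    "universes differ")
})

test_that("intersection sets match a brute-force conjunction oracle", {
  set.seed(6)
  for (trial in 1:20) {
    g <- sprintf("g%03d", 1:60)
    res <- lapply(c("T2", "T3", "T4"), function(o) {
      fake_result(g, round(rnorm(60, 0, 0.5), 2),
                  round(runif(60), 2), other = o)
    })
    set <- build_intersection_set(res, fdr_max = 0.3, lfc_min = 0.2)
    over_oracle <- under_oracle <- character(0)
    for (i in seq_along(g)) {
      ok_fdr <- all(sapply(res, function(r) r$FDR[i] <= 0.3))
      up <- all(sapply(res, function(r) r$logFC[i] >= 0.2))
      dn <- all(sapply(res, function(r) r$logFC[i] <= -0.2))
      if (ok_fdr && up) over_oracle <- c(over_oracle, g[i])
      if (ok_fdr && dn) under_oracle <- c(under_oracle, g[i])
    }
    expect_identical(set$over, over_oracle)
    expect_identical(set$under, under_oracle)
  }
})

test_that("relaxing thresholds never shrinks an intersection set", {
  set.seed(7)
  g <- sprintf("g%03d", 1:80)
  res <- lapply(c("T2", "T3", "T4"), function(o) {
    fake_result(g, rnorm(80, 0, 0.5), runif(80), other = o)
  })
  strict <- build_intersection_set(res, fdr_max = 0.1, lfc_min = 0.4)
  loose_fdr <- build_intersection_set(res, fdr_max = 0.3, lfc_min = 0.4)
  loose_lfc <- build_intersection_set(res, fdr_max = 0.1, lfc_min = 0.1)
  expect_true(all(strict$over %in% loose_fdr$over))
  expect_true(all(strict$under %in% loose_fdr$under))
  expect_true(all(strict$over %in% loose_lfc$over))
  expect_true(all(strict$under %in% loose_lfc$under))
})

test_that("shared extreme genes carry per-set directions", {
  mk <- function(over, under, focal) {
    structure(list(focal = focal, stage = "S1", over = over, under = under,
                   fdr_max = 0.1, lfc_min = 0.2,
                   table = tibble::tibble(gene_id = c(over, under),
                                          direction = rep(c("over", "under"),
                                                          c(length(over),
                                                            length(under))),
                                          mean_logFC = 0)),
              class = "intersection_set")
  }
  a <- mk(c("g1", "g2"), c("g3"), "T1")
  b <- mk(c("g4"), c("g2", "g5"), "T2")
  sh <- shared_extreme_genes(a, b)
  expect_equal(sh$gene_id, "g2")
  expect_equal(sh$direction_A, "over")
  expect_equal(sh$direction_B, "under")

  disjoint <- shared_extreme_genes(a, mk("g9", "g8", "T2"))
  expect_equal(nrow(disjoint), 0)

  b_other_stage <- mk("g1", character(0), "T2")
  b_other_stage$stage <- "S2"
  expect_error(shared_extreme_genes(a, b_other_stage), "stages")

  # full-union oracle on random sets
  set.seed(8)
  for (trial in 1:10) {
    g <- sprintf("g%02d", 1:30)
    sa <- mk(sample(g, 8), sample(setdiff(g, ""), 5), "T1")
    sb <- mk(sample(g, 6), sample(g, 7), "T2")
    got <- shared_extreme_genes(sa, sb)$gene_id
    oracle <- sort(intersect(c(sa$over, sa$under), c(sb$over, sb$under)))
    expect_identical(got, oracle)
  }
})

test_that("constitutive classification matches hand enumeration on a toy", {
  # 12 genes; sets at 4 stages; mean logFC signs constructed by hand:
  #  g01 in S1+S3, positive at all stages      -> multi, constitutive
  #  g02 in S1+S3, sign flips at S4            -> multi, not constitutive
  #  g03 in S1 only                            -> single stage
  #  g04 in all 4, negative everywhere         -> multi, constitutive
  #  g05 in S2+S4, missing logFC at S1         -> multi, diagnostics
  #  g06..g12 single-stage fillers
  mk <- function(over, under, stage) {
    structure(list(focal = "T1", stage = stage, over = over, under = under,
                   fdr_max = 0.1, lfc_min = 0.2,
                   table = tibble::tibble()), class = "intersection_set")
  }
  sets <- list(mk(c("g01", "g02", "g03", "g06"), c("g04"), "S1"),
               mk(c("g05", "g07", "g08"), c("g04", "g09"), "S2"),
               mk(c("g01", "g02", "g10"), c("g04", "g11"), "S3"),
               mk(c("g05"), c("g04", "g12"), "S4"))
  lfc <- tidyr::expand_grid(gene_id = sprintf("g%02d", 1:12),
                            stage = paste0("S", 1:4)) %>%
    dplyr::mutate(mean_logFC = 0.5)
  lfc$mean_logFC[lfc$gene_id == "g02" & lfc$stage == "S4"] <- -0.5
  lfc$mean_logFC[lfc$gene_id == "g04"] <- -0.8
  lfc <- lfc[!(lfc$gene_id == "g05" & lfc$stage == "S1"), ]

  rep <- suppressMessages(classify_constitutive(sets, lfc))
  expect_equal(length(rep$union), 12)
  expect_setequal(rep$multi_stage, c("g01", "g02", "g04", "g05"))
  expect_equal(rep$percent_multi, 4 / 12 * 100)
  expect_setequal(rep$constitutive, c("g01", "g04"))
  expect_equal(rep$diagnostics, "g05")
  expect_true(all(rep$multi_stage %in% rep$union))
})
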