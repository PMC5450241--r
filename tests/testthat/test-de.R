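unit_factors <- function(m, lib = 1e6) {
  tibble::tibble(sample_id = colnames(m), lib_size = rep(lib, ncol(m)),
                 factor = 1)
}

test_that("common dispersion vanishes for Poisson data", {
  set.seed(10)
  m <- matrix(rpois(1500 * 8, lambda = 200), 1500, 8,
              dimnames = list(sprintf("g%04d", 1:1500), paste0("s", 1:8)))
  groups <- rep(c("A", "B"), each = 4)
  est <- estimate_common_dispersion(m, groups, unit_factors(m))
  expect_lt(est, 0.01)
})

test_that("common dispersion recovers the generating value", {
  sim <- simulate_experiment(sim_config(
    n_genes = 2000, n_taxa = 2, n_stages = 1, n_reps = 4,
    dispersion_intercept = 0.1, dispersion_slope = 0, de_fraction = 0,
    seed = 8))
  fac <- tmm_factors(sim$counts)
  est <- estimate_common_dispersion(sim$counts, sim$samples$taxon, fac)
  expect_gt(est, 0.08)
  expect_lt(est, 0.12)
})

test_that("1-D dispersion optimisation matches a dense grid search", {
  set.seed(4)
  y <- matrix(rnbinom(8, mu = 150, size = 8), 1, 8,
              dimnames = list("g1", paste0("s", 1:8)))
  groups <- rep(c("A", "B"), each = 4)
  fac <- unit_factors(y)
  est <- estimate_common_dispersion(y, groups, fac)
  grid <- exp(seq(log(1e-4), log(5), length.out = 1e4))
  ll <- vapply(grid, function(phi) {
    oracle_nb_group_ll(y[1, ], log(rep(1e6, 8)), groups, phi, adjust = TRUE)
  }, numeric(1))
  best <- grid[which.max(ll)]
  # agree within the grid's own resolution
  expect_equal(log(est), log(best), tolerance = 2 * diff(log(grid[1:2])))
})

test_that("tagwise shrinkage interpolates between MLE and common", {
  sim <- simulate_experiment(sim_config(
    n_genes = 300, n_taxa = 2, n_stages = 1, n_reps = 4,
    dispersion_intercept = 0.15, dispersion_slope = 0, de_fraction = 0,
    seed = 12))
  fac <- tmm_factors(sim$counts)
  grp <- sim$samples$taxon
  common <- estimate_common_dispersion(sim$counts, grp, fac)

  # infinite prior weight collapses every gene onto the common value
  inf <- estimate_tagwise_dispersions(sim$counts, grp, fac, common,
                                      prior_weight = 1e9)
  expect_equal(inf$tagwise$dispersion, rep(common, 300), tolerance = 1e-6)

  # zero prior weight equals the per-gene grid-search MLE
  zero <- estimate_tagwise_dispersions(sim$counts, grp, fac, common,
                                       prior_weight = 0)
  grid <- common * 2^seq(-8, 8, length.out = 65)
  offsets <- log(fac$lib_size * fac$factor)
  for (g in sample(1:300, 12)) {
    ll <- vapply(grid, function(phi) {
      oracle_nb_group_ll(sim$counts[g, ], offsets, grp, phi, adjust = TRUE)
    }, numeric(1))
    expect_equal(zero$tagwise$dispersion[g], grid[which.max(ll)])
  }
})

test_that("shrunken dispersions order heterogeneous truth correctly", {
  set.seed(31)
  n <- 400
  phi_true <- rep(c(0.05, 0.4), each = n / 2)
  m <- matrix(rnbinom(n * 8, mu = 300, size = rep(1 / phi_true, 8)), n, 8,
              dimnames = list(sprintf("g%04d", 1:n), paste0("s", 1:8)))
  groups <- rep(c("A", "B"), each = 4)
  fac <- unit_factors(m)
  common <- estimate_common_dispersion(m, groups, fac)
  disp <- estimate_tagwise_dispersions(m, groups, fac, common)$tagwise
  lo <- disp$dispersion[1:(n / 2)]
  hi <- disp$dispersion[(n / 2 + 1):n]
  # fraction of cross-pairs ordered consistently with truth
  frac <- mean(outer(lo, hi, `<`))
  expect_gt(frac, 0.9)
})

test_that("identical groups give null results and swapping flips sign", {
  sim <- tiny_experiment(n_genes = 150, de_fraction = 0.15,
                         effect_size_log2 = 1)
  fac <- tmm_factors(sim$counts)
  grp <- sim$samples$taxon
  common <- estimate_common_dispersion(sim$counts, grp, fac)
  disp <- estimate_tagwise_dispersions(sim$counts, grp, fac, common)

  ab <- test_pairwise(sim$counts, sim$samples, "T1", "T2", fac, disp)
  ba <- test_pairwise(sim$counts, sim$samples, "T2", "T1", fac, disp)
  expect_equal(ab$logFC, -ba$logFC)
  expect_equal(ab$PValue, ba$PValue)
  expect_true(all(ab$PValue >= 0 & ab$PValue <= 1))

  # same data in both groups: logFC 0, p 1
  first4 <- sim$samples$sample_id[1:4]
  twin <- cbind(sim$counts[, first4], sim$counts[, first4])
  colnames(twin) <- paste0("c", 1:8)
  twin_samples <- tibble::tibble(sample_id = paste0("c", 1:8),
                                 taxon = rep(c("A", "B"), each = 4))
  twin_fac <- tibble::tibble(sample_id = paste0("c", 1:8),
                             lib_size = rep(fac$lib_size[1:4], 2),
                             factor = rep(fac$factor[1:4], 2))
  tw <- test_pairwise(twin, twin_samples, "A", "B", twin_fac, 0.1)
  expect_equal(tw$logFC, rep(0, nrow(twin)))
  expect_equal(tw$PValue, rep(1, nrow(twin)))

  expect_error(test_pairwise(sim$counts, sim$samples, "T1", "nope", fac,
                             disp), "unknown taxon")
})

test_that("LRT statistic matches a brute-force grid likelihood oracle", {
  y <- matrix(c(10, 12, 9, 11, 30, 28, 33, 35), 1, 8,
              dimnames = list("g1", paste0("s", 1:8)))
  samples <- tibble::tibble(sample_id = paste0("s", 1:8),
                            taxon = rep(c("A", "B"), each = 4))
  fac <- unit_factors(y)
  res <- test_pairwise(y, samples, "A", "B", fac, 0.1)

  grid <- seq(-14, -9, length.out = 5e4)
  ll_at <- function(counts) {
    max(vapply(grid, function(b) {
      sum(dnbinom(counts, size = 10, mu = exp(b + log(1e6)), log = TRUE))
    }, numeric(1)))
  }
  ll_null <- ll_at(y[1, ])
  ll_alt <- ll_at(y[1, 1:4]) + ll_at(y[1, 5:8])
  lrt_oracle <- 2 * (ll_alt - ll_null)
  lrt_got <- qchisq(res$PValue, df = 1, lower.tail = FALSE)
  expect_equal(lrt_got, lrt_oracle, tolerance = 1e-4)
  expect_gte(lrt_got, 0)
})

test_that("BH adjustment matches the hand computation", {
  expect_equal(adjust_fdr(0.03), 0.03)
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  set.seed(2)
  p <- runif(200)^2
  expect_equal(adjust_fdr(p), oracle_bh(p))
  # permutation equivariance
  perm <- sample(200)
  expect_equal(adjust_fdr(p[perm]), adjust_fdr(p)[perm])
  expect_error(adjust_fdr(c(0.5, 1.2)), "0, 1")
  expect_error(adjust_fdr(c(0.5, -0.1)), "0, 1")
})

test_that("planted effects are recovered with small bias", {
  sim <- simulate_experiment(sim_config(
    n_genes = 800, n_taxa = 2, n_stages = 1, n_reps = 4,
    de_fraction = 0.5, effect_size_log2 = 1, focal_taxa = "T1",
    baseline_log_mean = 5.5, baseline_log_sd = 0.8, seed = 44))
  fac <- tmm_factors(sim$counts)
  grp <- sim$samples$taxon
  common <- estimate_common_dispersion(sim$counts, grp, fac)
  disp <- estimate_tagwise_dispersions(sim$counts, grp, fac, common,
                                       anchor = "trend")
  res <- test_pairwise(sim$counts, sim$samples, "T1", "T2", fac, disp)
  truth <- sim$truth[sim$truth$taxon == "T1", ]
  tru <- truth$log2fc[match(res$gene_id, truth$gene_id)]
  well <- sim$gene_truth$baseline_cpm >= 50
  sel <- tru != 0 & well[match(res$gene_id, sim$gene_truth$gene_id)]
  expect_lt(abs(mean(res$logFC[sel] - tru[sel])), 0.1)
})
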