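# Internal negative-binomial GLM machinery.
#
# All models here are intercept-only NB regressions with known per-sample
# offsets (log effective library size) and fixed dispersion: mu_gs =
# exp(beta_g + o_s). The mean is profiled out by Newton scoring on beta_g,
# vectorised across genes; the score and expected information are
#   U(beta)  = sum_s (y - mu) / (1 + phi mu)
#   I(beta)  = sum_s  mu      / (1 + phi mu).

# Fit one shared mean per gene across the given samples. Returns per-gene
# log-likelihood (and the fitted log-rate). With adjust = TRUE the
# Cox-Reid adjustment -0.5 log I(beta-hat) is applied, removing the
# leading-order bias that plugging in estimated means induces when the
# likelihood is used to estimate the dispersion.
nb_profile_loglik <- function(y, offsets, phi, adjust = FALSE) {
  if (!is.matrix(y)) y <- matrix(y, nrow = 1)
  stopifnot(length(offsets) == ncol(y))
  phi <- rep_len(phi, nrow(y))
  tot <- rowSums(y)
  pos <- tot > 0
  ll <- numeric(nrow(y))
  beta <- rep(NA_real_, nrow(y))
  if (any(pos)) {
    yp <- y[pos, , drop = FALSE]
    php <- phi[pos]
    b <- log(rowSums(yp) / sum(exp(offsets)))
    off <- matrix(offsets, nrow(yp), ncol(yp), byrow = TRUE)
    for (it in 1:100) {
      mu <- exp(b + off)
      denom <- 1 + php * mu
      step <- rowSums((yp - mu) / denom) / pmax(rowSums(mu / denom), 1e-12)
      step <- pmin(pmax(step, -5), 5)
      b <- b + step
      if (max(abs(step)) < 1e-12) break
    }
    mu <- exp(b + off)
    ll[pos] <- rowSums(dnbinom(yp, size = 1 / php, mu = mu, log = TRUE))
    if (adjust) {
      ll[pos] <- ll[pos] - 0.5 * log(rowSums(mu / (1 + php * mu)))
    }
    beta[pos] <- b
  }
  # All-zero genes: mu -> 0 gives likelihood 1 at every observation (and
  # carry no information about the dispersion, so no adjustment).
  list(loglik = ll, beta = beta)
}

# Per-gene log-likelihood with a separate profiled mean per group.
nb_group_loglik <- function(y, offsets, groups, phi, adjust = FALSE) {
  groups <- as.character(groups)
  ll <- numeric(nrow(y))
  for (g in unique(groups)) {
    j <- groups == g
    ll <- ll + nb_profile_loglik(y[, j, drop = FALSE], offsets[j], phi,
                                 adjust = adjust)$loglik
  }
  ll
}

# Effective-library-size offsets from a tmm_factors() tibble, aligned to the
# columns of m.
nb_offsets <- function(m, factors) {
  idx <- match(colnames(m), factors$sample_id)
  if (anyNA(idx)) abort("normalization factors missing for some samples")
  log(factors$lib_size[idx] * factors$factor[idx])
}
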