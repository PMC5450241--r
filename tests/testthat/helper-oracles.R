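# Independent reference implementations used as oracles. These are written
# from the definitions, deliberately naive (loops, sorting, grid search),
# and share no code with the package internals they check.

# Clean-room TMM: literal trimmed weighted mean of M-values.
oracle_tmm <- function(m, lib_sizes = colSums(m)) {
  n <- ncol(m)
  f75 <- sapply(seq_len(n), function(j) {
    unname(quantile(m[, j], 0.75)) / lib_sizes[j]
  })
  ref <- which.min(abs(f75 - mean(f75)))
  raw <- sapply(seq_len(n), function(j) {
    obs <- m[, j]; refc <- m[, ref]
    keep <- obs > 0 & refc > 0
    obs <- obs[keep]; refc <- refc[keep]
    no <- lib_sizes[j]; nr <- lib_sizes[ref]
    M <- log2((obs / no) / (refc / nr))
    A <- 0.5 * log2((obs / no) * (refc / nr))
    w <- 1 / ((no - obs) / (no * obs) + (nr - refc) / (nr * refc))
    if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
    nM <- length(M)
    loM <- floor(nM * 0.30) + 1; hiM <- nM + 1 - loM
    loA <- floor(nM * 0.05) + 1; hiA <- nM + 1 - loA
    keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    if (!any(keep2)) return(1)
    2^(sum(M[keep2] * w[keep2]) / sum(w[keep2]))
  })
  raw / exp(mean(log(raw)))
}

# Literal NB profile log-likelihood: 1-D optimize over the log-mean, plain
# dnbinom sum; optional Cox-Reid term computed from the definition.
oracle_nb_profile_ll <- function(y, offsets, phi, adjust = FALSE) {
  if (sum(y) == 0) return(0)
  f <- function(lb) {
    mu <- exp(lb + offsets)
    ll <- sum(dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
    if (adjust) ll <- ll - 0.5 * log(sum(mu / (1 + phi * mu)))
    ll
  }
  optimize(f, c(-30, 30), maximum = TRUE, tol = 1e-10)$objective
}

# Group version of the above.
oracle_nb_group_ll <- function(y, offsets, groups, phi, adjust = FALSE) {
  sum(sapply(unique(groups), function(g) {
    j <- groups == g
    oracle_nb_profile_ll(y[j], offsets[j], phi, adjust)
  }))
}

# Naive quadratic running-sum enrichment score.
oracle_es <- function(ids, geneset) {
  hit <- ids %in% geneset
  G <- sum(hit); N <- length(ids)
  running <- numeric(N)
  nh <- 0L
  for (i in seq_len(N)) {
    if (hit[i]) nh <- nh + 1L
    running[i] <- nh / G - (i - nh) / (N - G)
  }
  best <- 0
  for (i in seq_len(N)) if (abs(running[i]) > abs(best)) best <- running[i]
  if (abs(max(running)) == abs(min(running)) && max(running) > 0) {
    best <- max(running)
  }
  best
}

# Per-base boolean-AND coverage scan.
oracle_joint_regions <- function(tracks, min_depth) {
  out <- list()
  for (s in sort(names(tracks[[1]]))) {
    len <- length(tracks[[1]][[s]])
    ok <- logical(len)
    for (i in seq_len(len)) {
      ok[i] <- all(sapply(tracks, function(t) t[[s]][i] >= min_depth))
    }
    start <- NULL
    for (i in seq_len(len)) {
      if (ok[i] && is.null(start)) start <- i
      if ((!ok[i] || i == len) && !is.null(start)) {
        end <- if (ok[i]) i else i - 1
        out[[length(out) + 1]] <- data.frame(scaffold = s, start = start - 1,
                                             end = end)
        start <- NULL
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer()))
  }
  do.call(rbind, out)
}

# Literal step-up BH from the definition q_i = min_{j >= i} m p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(sapply(i:m, function(j) m * p[o[j]] / j))
  }
  pmin(q, 1)
}

# Small simulated experiment shared by several test files.
tiny_experiment <- function(n_genes = 400, seed = 99, ...) {
  simulate_experiment(sim_config(n_genes = n_genes, n_taxa = 4, n_stages = 1,
                                 n_reps = 4, seed = seed, ...))
}
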