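# Independent brute-force oracles. Each recomputes a quantity by the
# most literal method available (triple loops, grid search, exhaustive
# enumeration) and is kept free of the package's own computation paths.

# Per-coarse-voxel fraction of fine voxels carrying `codes`, by explicit
# triple loop over coarse voxels.
oracle_fractions <- function(labels, codes, f) {
  d <- dim(labels)
  dc <- d / f
  out <- array(0, dim = dc)
  for (i in seq_len(dc[1])) for (j in seq_len(dc[2]))
    for (k in seq_len(dc[3])) {
      block <- labels[(i - 1) * f + 1:f, (j - 1) * f + 1:f,
                      (k - 1) * f + 1:f]
      out[i, j, k] <- sum(block %in% codes) / f^3
    }
  out
}

# Coarse label by largest-fraction argmax (ties to the smaller code).
oracle_transfer <- function(labels, f, threshold) {
  codes <- sort(setdiff(unique(as.vector(labels)), 0L))
  d <- dim(labels)
  dc <- d / f
  out <- array(0L, dim = dc)
  for (i in seq_len(dc[1])) for (j in seq_len(dc[2]))
    for (k in seq_len(dc[3])) {
      block <- labels[(i - 1) * f + 1:f, (j - 1) * f + 1:f,
                      (k - 1) * f + 1:f]
      fr <- vapply(codes, function(cd) sum(block == cd) / f^3, numeric(1))
      ok <- which(fr >= threshold)
      if (length(ok)) {
        best <- ok[which.max(fr[ok])]  # which.max takes the first = smallest code
        out[i, j, k] <- codes[best]
      }
    }
  out
}

# Exhaustive T1 grid search with (S0, offset) profiled by linear least
# squares at each candidate T1.
oracle_t1_grid <- function(times, signals, grid = seq(1, 100, by = 0.01)) {
  best <- c(t1 = NA_real_, sse = Inf)
  for (t1 in grid) {
    x <- 1 - exp(-times / t1)
    fit <- stats::lm.fit(cbind(x, 1), signals)
    sse <- sum(fit$residuals^2)
    if (sse < best["sse"]) best <- c(t1 = t1, sse = sse)
  }
  best
}

# Best SSE over n random (ps, T2s, T2l) draws with (S0, offset) profiled.
oracle_biexp_random <- function(times, signals, n = 1e4, seed = 99) {
  set.seed(seed)
  ps <- runif(n, 0.01, 0.99)
  t2s <- runif(n, 0.05, 20)
  t2l <- t2s + runif(n, 0, 40)
  best <- Inf
  for (i in seq_len(n)) {
    x <- ps[i] * exp(-times / t2s[i]) + (1 - ps[i]) * exp(-times / t2l[i])
    fit <- stats::lm.fit(cbind(x, 1), signals)
    sse <- sum(fit$residuals^2)
    if (sse < best) best <- sse
  }
  best
}

# Friedman statistic written out long-hand (no ties assumed) and the
# exact permutation p-value by enumeration of all within-row orderings.
oracle_friedman_exact <- function(values) {
  n <- nrow(values); k <- ncol(values)
  stat_fn <- function(v) {
    R <- colSums(t(apply(v, 1, rank)))
    12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  }
  obs <- stat_fn(values)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  idx <- expand.grid(rep(list(1:6), n))
  count <- 0L
  for (g in seq_len(nrow(idx))) {
    v <- values
    for (i in seq_len(n)) v[i, ] <- values[i, perms[idx[g, i], ]]
    if (stat_fn(v) >= obs - 1e-12) count <- count + 1L
  }
  count / nrow(idx)
}

# Exact two-sided paired signed-rank p by enumerating all sign vectors
# (no zero differences, no tied magnitudes).
oracle_signed_rank_exact <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-12)
}

# Seeded Gaussian noise array (for registration trials).
with_seed_rnorm <- function(seed, d, sigma) {
  set.seed(seed)
  array(stats::rnorm(prod(d), 0, sigma), dim = d)
}
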