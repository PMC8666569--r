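# Shared fixtures and independent oracles used across test files.

default_pool <- build_tone_pool()

# All permutations of 1..n (for exhaustive assignment enumeration).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# Brute-force EMD oracle: minimum mean assignment cost over all n!
# permutations, built directly from the ground-cost definition.
emd_brute <- function(fa, fb, metric = ground_metric()) {
  n <- length(fa)
  pa <- log(fa / metric$ref_hz) / log(metric$step_ratio)
  pb <- log(fb / metric$ref_hz) / log(metric$step_ratio)
  if (metric$pitch_scale == "semitones") {
    pa <- 12 * log2(fa / metric$ref_hz); pb <- 12 * log2(fb / metric$ref_hz)
  } else if (metric$pitch_scale == "log_hz") {
    pa <- log(fa); pb <- log(fb)
  }
  pos <- seq_len(n)
  cost <- metric$position_weight * abs(outer(pos, pos, "-")) +
    metric$pitch_weight * abs(outer(pa, pb, "-"))
  perms <- all_perms(n)
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    best <- min(best, sum(cost[cbind(pos, perms[r, ])]))
  }
  best / n
}

# Benjamini-Hochberg step-up oracle straight from the definition:
# adjusted p_(i) = min(1, min_{k >= i} m * p_(k) / k).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Minimum-norm least-squares oracle via the SVD pseudoinverse.
pinv_solve <- function(X, y) {
  s <- svd(X)
  keep <- s$d > max(dim(X)) * .Machine$double.eps * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    ((crossprod(s$u[, keep, drop = FALSE], y)) / s$d[keep])
}

# Small, fast simulation settings for module tests.
tiny_design <- function(seed = 1) {
  build_design(n_runs = 2, trials_per_run = 6, seed = seed, delays_s = 3)
}

tiny_params <- function(...) {
  sim_params(n_voxels = c(aud = 12L), ...)
}
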