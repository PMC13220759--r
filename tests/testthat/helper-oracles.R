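# Independent brute-force oracles used across the suite.

# Exhaustive double loop over variant pairs and cases (the definition of
# the weighted interaction burden), independent of the package's
# factorized evaluation.
brute_rvib <- function(gi, gj, wi = rep(1, nrow(gi)), wj = rep(1, nrow(gj))) {
  gi[is.na(gi)] <- 0; gj[is.na(gj)] <- 0
  total <- 0
  for (k in seq_len(ncol(gi))) {
    best <- 0
    for (p in seq_len(nrow(gi))) for (q in seq_len(nrow(gj))) {
      v <- wi[p] * gi[p, k] * wj[q] * gj[q, k]
      if (v > best) best <- v
    }
    total <- total + best
  }
  total
}

# Direct-summation truncated NB pmf: renormalize dnbinom by explicitly
# summed truncation mass.
brute_tnb_pmf <- function(y, mu, theta, t) {
  if (y <= t) return(0)
  mass_below <- if (t < 0) 0 else sum(dnbinom(0:t, size = theta, mu = mu))
  dnbinom(y, size = theta, mu = mu) / (1 - mass_below)
}

# Rank-based MLFC computed straight from its definition.
brute_mlfc <- function(p) {
  n <- length(p)
  mean(abs(log2(sort(p) / (seq_len(n) / (n + 1)))))
}

# Tiny two-gene genotype instance generator for property tests.
random_instance <- function(n_vi, n_vj, n_cases, seed) {
  set.seed(seed)
  list(
    gi = matrix(sample(0:2, n_vi * n_cases, replace = TRUE,
                       prob = c(0.90, 0.08, 0.02)), n_vi, n_cases),
    gj = matrix(sample(0:2, n_vj * n_cases, replace = TRUE,
                       prob = c(0.90, 0.08, 0.02)), n_vj, n_cases),
    wi = sample(0:6, n_vi, replace = TRUE),
    wj = sample(0:6, n_vj, replace = TRUE)
  )
}

# Simulate counts from a truncated NB by rejection (test-only).
rtnb <- function(n, mu, theta, t) {
  y <- rnbinom(n, size = theta, mu = mu)
  bad <- which(y <= t)
  while (length(bad)) {
    y[bad] <- rnbinom(length(bad), size = theta, mu = mu[bad])
    bad <- bad[y[bad] <= t]
  }
  y
}
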