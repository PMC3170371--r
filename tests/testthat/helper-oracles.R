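# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's own code paths.

# exhaustive enumeration of the binomial percentile: smallest k with
# CDF(k) >= 1 - alpha, by summing the pmf term by term
oracle_binomial_percentile <- function(S, gamma, alpha) {
  cdf <- cumsum(dbinom(0:S, S, gamma))
  (0:S)[which(cdf >= 1 - alpha - 1e-12)[1]]
}

# brute-force gamma0: evaluate K_gamma - gamma at every distinct p in (0,1)
oracle_gamma0 <- function(p) {
  cand <- sort(unique(p))
  cand <- cand[cand > 0 & cand < 1]
  d <- vapply(cand, function(g) mean(p <= g) - g, numeric(1))
  cand[which.max(d)]
}

# brute-force q-values: double loop over thresholds at observed p-values
oracle_qvalues <- function(p, pi0 = 1, robust = TRUE) {
  S <- length(p)
  ep <- function(t) {
    r <- sum(p <= t)
    cc <- if (robust) 1 - (1 - t)^S else 1
    if (t == 0) 0 else min(1, pi0 * S * t / (r * cc))
  }
  vapply(p, function(pi) {
    min(vapply(p[p >= pi], ep, numeric(1)))
  }, numeric(1))
}

# empirical single-test rejection rate by direct simulation
oracle_power_mc <- function(n, x, alpha, n_rep, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * n_rep, mean = x), nrow = n)
  mu <- colMeans(m)
  v <- (colSums(m^2) - n * mu^2) / (n - 1)
  tt <- mu / sqrt(v / n)
  mean(2 * pt(-abs(tt), n - 1) <= alpha)
}
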