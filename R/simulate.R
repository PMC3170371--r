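#' Define a simulation scenario for the t-test power/FDR study
#'
#' Bundles the parameters of the synthetic-data design used throughout the
#' power and pFDR experiments: a family of `S` one-sample two-tailed t-tests
#' of H0: mean 0, each on `n` draws from N(0, 1) (true null) or
#' N(`effect_size`, 1) (true effect). A fixed fraction of tests carries
#' effects; by default the effect size is 0.36, a weak effect calibrated so
#' that a single test at the 5% level has power about 0.10 asymptotically.
#'
#' @param S Number of tests per family.
#' @param n Sample size per test (at least 2).
#' @param effect_size Mean of the alternative normal (default 0.36).
#' @param effect_fraction Proportion of tests with true effects, in \[0, 1\].
#' @param alpha Level used by the adjustment methods (default 0.05).
#' @param n_replicates Number of replicate families (default 1000).
#' @param seed Root seed for the generator (default 1).
#' @return A list of class `"simulation_scenario"`.
#' @export
simulation_scenario <- function(S, n, effect_size = 0.36, effect_fraction = 0,
                                alpha = 0.05, n_replicates = 1000, seed = 1) {
  stopifnot(S >= 1, n >= 2, effect_fraction >= 0, effect_fraction <= 1,
            n_replicates >= 1)
  check_alpha(alpha)
  structure(list(S = as.integer(S), n = as.integer(n),
                 effect_size = as.numeric(effect_size),
                 effect_fraction = as.numeric(effect_fraction),
                 alpha = as.numeric(alpha),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf(
    "t-test simulation scenario: S = %d, n = %d, effect N(%g, 1) in %.0f%% of tests,\n  alpha = %g, %d replicates, seed %d\n",
    x$S, x$n, x$effect_size, 100 * x$effect_fraction, x$alpha,
    x$n_replicates, x$seed))
  invisible(x)
}

#' Two-tailed one-sample t-test p-value via the incomplete beta function
#'
#' Tests H0: population mean 0 against a two-sided alternative. The t
#' statistic is mapped to a p-value through the regularized incomplete beta
#' identity `p = I_{df/(df + t^2)}(df/2, 1/2)` with `df = n - 1`, the direct
#' transform classically used when tabulating two-tailed t probabilities.
#'
#' @param x Numeric sample of length at least 2 with nonzero variance.
#' @return Two-tailed p-value in \[0, 1\].
#' @examples
#' ttest_pvalue(c(-1, 0, 1))        # mean 0 -> p = 1
#' @export
ttest_pvalue <- function(x) {
  if (!is.numeric(x) || length(x) < 2L || anyNA(x)) {
    stop("sample must be numeric of length >= 2 without NA", call. = FALSE)
  }
  s <- stats::sd(x)
  if (s == 0) stop("sample has zero variance; t statistic undefined", call. = FALSE)
  n <- length(x)
  t <- mean(x) / (s / sqrt(n))
  df <- n - 1
  stats::pbeta(df / (df + t^2), df / 2, 0.5)
}

# vectorized p-values for a matrix of samples (columns = tests)
ttest_pvalue_matrix <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  # column sds without apply(): E[x^2] - mean^2, with the n/(n-1) correction
  v <- (colSums(m^2) - n * mu^2) / (n - 1)
  t2 <- n * mu^2 / v
  df <- n - 1
  stats::pbeta(df / (df + t2), df / 2, 0.5)
}

# deterministic per-replicate seed derived from the root seed and the
# replicate counter (a Weyl-style integer mix, kept below 2^31)
replicate_seed <- function(seed, replicate_index) {
  as.integer((as.double(seed) * 1000003 + as.double(replicate_index) * 7919) %%
               .Machine$integer.max)
}

#' Generate one replicate family of t-test p-values with truth labels
#'
#' Draws one family under the scenario's mixture design: exactly
#' `round(S * effect_fraction)` tests (the first ones, by index) sample from
#' N(`effect_size`, 1), the rest from N(0, 1); each test's `n` draws are
#' reduced to a two-tailed one-sample t-test p-value. The output is
#' deterministic given `(scenario$seed, replicate_index)` and independent of
#' the caller's RNG state, so individual replicates are reproducible without
#' generating their predecessors.
#'
#' @param scenario A [simulation_scenario()].
#' @param replicate_index Positive integer identifying the replicate.
#' @return List with `p` (numeric vector of length `S`), `effect` (logical
#'   truth labels, `TRUE` for tests carrying an effect), and
#'   `replicate_index`.
#' @export
generate_family <- function(scenario, replicate_index = 1) {
  stopifnot(inherits(scenario, "simulation_scenario"), replicate_index >= 1)
  S <- scenario$S
  n <- scenario$n
  n_eff <- round(S * scenario$effect_fraction)
  effect <- c(rep(TRUE, n_eff), rep(FALSE, S - n_eff))
  p <- with_seed(replicate_seed(scenario$seed, replicate_index), {
    m <- matrix(stats::rnorm(n * S), nrow = n)
    if (n_eff > 0) {
      m[, seq_len(n_eff)] <- m[, seq_len(n_eff), drop = FALSE] + scenario$effect_size
    }
    ttest_pvalue_matrix(m)
  })
  list(p = as_pvalues(p), effect = effect,
       replicate_index = as.integer(replicate_index))
}

#' Exact power of a single one-sample two-tailed t-test
#'
#' Closed-form power against a shift alternative N(`x`, 1) via the noncentral
#' t distribution with noncentrality `x * sqrt(n)` and `n - 1` degrees of
#' freedom. For the weak effect `x = 0.36` at `alpha = 0.05` this gives the
#' per-test powers 0.10, 0.18, 0.33 and 0.95 at sample sizes 5, 10, 20 and
#' 100 (to two decimals) — the anchor values of the simulation design.
#'
#' @param n Sample size (at least 2).
#' @param x Effect size (mean of the alternative normal, unit variance).
#' @param alpha Per-test level in (0, 1).
#' @return Rejection probability in \[0, 1\].
#' @examples
#' single_test_power(100, 0.36, 0.05) # ~0.95
#' @export
single_test_power <- function(n, x, alpha = 0.05) {
  stopifnot(n >= 2)
  alpha <- check_alpha(alpha)
  df <- n - 1
  ncp <- x * sqrt(n)
  tc <- stats::qt(1 - alpha / 2, df)
  (1 - stats::pt(tc, df, ncp)) + stats::pt(-tc, df, ncp)
}
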