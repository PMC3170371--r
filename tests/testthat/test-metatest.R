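test_that("empirical exceedance counts with the closed convention", {
  expect_equal(empirical_exceedance(c(0.01, 0.03, 0.2, 0.7), 0.05), 0.5)
  expect_equal(empirical_exceedance(runif(50), 1), 1)
  expect_equal(empirical_exceedance(c(0.5, 0.6), 0), 0)
  expect_equal(empirical_exceedance(c(0.05, 0.1), 0.05), 0.5) # p == gamma counts
  expect_error(empirical_exceedance(numeric(0), 0.5), "empty")
  expect_error(empirical_exceedance(c(0.1), 1.5), "gamma")
})

test_that("exceedance is a nondecreasing right-continuous step function of gamma", {
  set.seed(41)
  p <- runif(30)
  g <- sort(c(p, p - 1e-9, runif(20)))
  g <- g[g >= 0 & g <= 1]
  k <- vapply(g, function(x) empirical_exceedance(p, x), numeric(1))
  expect_true(all(diff(k) >= 0))
  expect_equal(empirical_exceedance(p, min(p) - 1e-9), 0)
  expect_equal(empirical_exceedance(p, max(p)), 1)
})

test_that("gamma0 selection maximizes the ECDF-uniform distance", {
  expect_equal(select_gamma0(c(0.01, 0.02, 0.9, 0.95)), 0.02)
  expect_equal(select_gamma0(c(0.2, 0.4, 0.6, 0.8)), 0.8)
  expect_equal(select_gamma0(0.5), 0.5)
  expect_warning(g <- select_gamma0(c(0, 1, 1)), "no valid gamma0")
  expect_true(is.na(g))
})

test_that("gamma0 matches brute-force enumeration on random instances", {
  set.seed(7)
  for (i in 1:1000) {
    S <- sample(2:40, 1)
    p <- round(runif(S)^sample(1:3, 1), 3) # rounding induces ties
    p <- pmin(pmax(p, 0), 1)
    if (all(p %in% c(0, 1))) next
    expect_identical(select_gamma0(p), oracle_gamma0(p))
  }
})

test_that("one-sided KS critical value behaves across levels and sizes", {
  expect_equal(ks_one_sided_critical(0.05, 100, exact = FALSE),
               sqrt(log(1 / 0.05) / 200), tolerance = 1e-12)
  expect_equal(ks_one_sided_critical(0.05, 100, exact = FALSE), 0.1224,
               tolerance = 1e-3)
  # exact and asymptotic agree to ~1% of a unit at moderate S
  expect_equal(ks_one_sided_critical(0.05, 100, exact = TRUE), 0.1224,
               tolerance = 0.02)
  # exact inversion really hits the Birnbaum-Tingey tail: for S = 1 the
  # distribution is P(D+ >= d) = 1 - d, so the critical value is 1 - alpha
  expect_equal(ks_one_sided_critical(0.05, 1, exact = TRUE), 0.95,
               tolerance = 1e-8)
  # smaller alpha -> larger critical distance; larger S -> smaller distance
  expect_gt(ks_one_sided_critical(0.01, 100), ks_one_sided_critical(0.05, 100))
  expect_gt(ks_one_sided_critical(0.05, 100), ks_one_sided_critical(0.05, 10000))
  expect_lt(ks_one_sided_critical(0.05, 1e7), 0.001)
  expect_error(ks_one_sided_critical(0, 100), "alpha")
  expect_error(ks_one_sided_critical(1, 100), "alpha")
})

test_that("exact KS critical value calibrates the null exceedance distance", {
  # MC check: under the complete null, the maximal K_gamma - gamma exceeds the
  # exact critical value with probability ~ alpha
  crit <- ks_one_sided_critical(0.05, 200, exact = TRUE)
  set.seed(99)
  hits <- vapply(1:2000, function(i) {
    u <- sort(runif(200))
    max(seq_len(200) / 200 - u) >= crit
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(mean(hits) - 0.05), 4 * se)
})

test_that("binomial critical count equals the percentile enumeration", {
  expect_identical(gof_critical_value(10, 0.5, 0.05, mode = "binomial"), 8L)
  expect_identical(gof_critical_value(100, 0.001, 0.05, mode = "binomial"), 1L)
  # extreme-percentile limit: alpha -> 0 pushes b to S
  expect_identical(gof_critical_value(20, 0.5, 1e-12, mode = "binomial"), 20L)
  # conservative rule guarantees size <= alpha
  S <- 100; g <- 0.05; a <- 0.05
  b_cons <- gof_critical_value(S, g, a, mode = "binomial", conservative = TRUE)
  expect_lte(1 - pbinom(b_cons - 1, S, g), a)
  expect_identical(b_cons, gof_critical_value(S, g, a, mode = "binomial") + 1L)
  expect_error(gof_critical_value(10, 0, 0.05), "gamma0")
  expect_error(gof_critical_value(10, 1, 0.05), "gamma0")
})

test_that("binomial critical count matches the oracle over S <= 200 and a 99-point grid", {
  grid <- seq(0.01, 0.99, by = 0.01)
  for (S in 1:200) {
    b <- vapply(grid, function(g) gof_critical_value(S, g, 0.05, mode = "binomial"),
                integer(1))
    b_or <- vapply(grid, function(g) oracle_binomial_percentile(S, g, 0.05),
                   numeric(1))
    if (!isTRUE(all.equal(as.numeric(b), b_or))) {
      fail(sprintf("mismatch at S = %d", S))
    }
  }
  succeed()
})

test_that("chi-squared mode reproduces the one-sided normal-deviate threshold", {
  expect_identical(gof_critical_value(100, 0.05, 0.05, mode = "chi2"), 9L)
  # agrees with direct inversion of the two-cell statistic
  S <- 500; g <- 0.1; a <- 0.01
  b <- gof_critical_value(S, g, a, mode = "chi2")
  stat <- function(k) (k - S * g)^2 / (S * g * (1 - g))
  expect_gte(stat(b), qnorm(1 - a)^2)
  expect_lt(stat(b - 1), qnorm(1 - a)^2)
  expect_gt(b, S * g)
  # auto mode: binomial below S = 10, chi-squared from 10 on
  expect_identical(sgof(runif(9, 0.5, 0.9))$gof_test_used, "binomial")
  expect_identical(sgof(runif(10, 0.5, 0.9))$gof_test_used, "chi-squared")
})

test_that("SGoF reproduces the worked examples", {
  expect_identical(sgof(rep(0.5, 100))$n_discoveries, 0L)
  p <- c(rep(0.001, 50), rep(0.9, 50))
  r <- sgof(p)
  expect_identical(r$n_discoveries, 42L) # S*K = 50, b = 9 => 50 - 9 + 1
  expect_identical(r$critical_value, 9L)
  expect_identical(sort(r$rejected_indices), 1:42)
  expect_true(all(p[r$rejected_indices] == 0.001))
  # no excess over expectation: observed count equals S*gamma exactly
  r2 <- sgof(c(rep(0.3, 5), rep(0.7, 5)), gamma = 0.5)
  expect_identical(r2$k_gamma0, 5L)
  expect_identical(r2$n_discoveries, 0L)
})

test_that("SGoF+ runs the guard, metatest and cap as specified", {
  p <- c(rep(0.001, 50), rep(0.9, 50))
  r <- sgof_plus(p)
  expect_identical(r$method_label, "SGoF+")
  expect_equal(r$gamma0, 0.001)
  expect_equal(r$ks_distance, 0.499)
  expect_equal(r$ks_critical, ks_one_sided_critical(0.05, 100))
  expect_true(r$ks_guard_passed)
  expect_identical(r$critical_value, 1L)
  expect_identical(r$n_discoveries, 50L) # min(50 - 1 + 1, S*K_alpha = 50)
  # all p-values at 1: nothing can be declared
  expect_warning(r1 <- sgof_plus(rep(1, 20)), "no valid gamma0")
  expect_identical(r1$n_discoveries, 0L)
  # uniform-ish spread with no excess: guard blocks discoveries
  r2 <- sgof_plus(seq(0.05, 0.95, length.out = 19))
  expect_false(r2$ks_guard_passed && r2$n_discoveries > 0 &&
                 r2$ks_distance < r2$ks_critical)
})

test_that("discoveries are a prefix of the sorted p-values and capped by K_alpha", {
  set.seed(13)
  for (i in 1:50) {
    S <- sample(c(20, 100, 500), 1)
    frac <- runif(1, 0, 0.5)
    p <- c(rbeta(round(S * frac), 0.2, 5), runif(S - round(S * frac)))
    r <- sgof_plus(p)
    expect_lte(r$n_discoveries, sum(p <= 0.05)) # cap invariant
    expect_lte(r$n_discoveries, r$k_alpha)
    if (r$n_discoveries > 0) {
      expect_true(r$ks_guard_passed)
      expect_identical(r$rejected_indices,
                       order(p)[seq_len(r$n_discoveries)])
      # prefix property: every rejected p <= every non-rejected p
      expect_lte(max(p[r$rejected_indices]),
                 min(p[-r$rejected_indices]))
    }
  }
})

test_that("tie handling at the rejection boundary is stable and optional", {
  p <- c(0.9, 0.001, 0.001, 0.001, 0.9, 0.001, rep(0.95, 14))
  r <- sgof(p, gof = "binomial")
  if (r$n_discoveries > 0 && r$n_discoveries < 4) {
    # stable input-order tie-break: earliest tied indices first
    expect_identical(r$rejected_indices,
                     c(2L, 3L, 4L, 6L)[seq_len(r$n_discoveries)])
  }
  r_all <- sgof(p, gof = "binomial", reject_ties = TRUE)
  if (r_all$n_discoveries > 0) {
    expect_setequal(setdiff(c(2L, 3L, 4L, 6L), r_all$rejected_indices),
                    integer(0))
  }
})
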