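test_that("plug-in pi0 at a single lambda follows the counting formula", {
  expect_equal(pi0_at_lambda(c(0.1, 0.2, 0.6, 0.8), 0.5), 1)
  expect_equal(pi0_at_lambda(c(0.3, 0.7, 0.9), 0), 1) # all p > 0
  expect_equal(pi0_at_lambda(c(0.9, 0.95), 0.5), 2) # unclipped by design
  expect_error(pi0_at_lambda(c(0.2, 0.4), 1), "lambda")
  expect_error(pi0_at_lambda(c(0.2, 0.4), -0.1), "lambda")
})

test_that("smoothing estimator is exact on flat curves and sane on extremes", {
  # constant pi0(lambda) across the grid -> the spline is that constant
  p <- rep(c(0.98, 0.99), 50) # all p above every grid point
  est <- pi0_smoothing(p, grid = seq(0, 0.9, 0.1))
  expect_equal(est$value, 1, tolerance = 1e-6) # clipped from a constant > 1
  # everything below the first nonzero grid point: pi0(lambda) is 0 on the
  # whole grid except the single point lambda = 0, and the spline at 1 is ~0
  p2 <- runif(1000, 0, 0.009)
  expect_lt(pi0_smoothing(p2)$value, 0.01)
  expect_error(pi0_smoothing(runif(10), grid = c(0, 0.3, 0.6)), "4 lambda")
  expect_error(pi0_smoothing(runif(10), grid = c(0.3, 0.2, 0.6, 0.9)),
               "strictly increasing")
})

test_that("bootstrap estimator is reproducible and handles degenerate ties", {
  set.seed(5)
  p <- runif(500)
  e1 <- pi0_bootstrap(p, n_boot = 50, seed = 11)
  e2 <- pi0_bootstrap(p, n_boot = 50, seed = 11)
  expect_identical(e1$value, e2$value)
  expect_identical(e1$tuning$lambda, e2$tuning$lambda)
  # a seeded call must not disturb the caller's RNG stream
  set.seed(42); a <- runif(1)
  set.seed(42); invisible(pi0_bootstrap(p, n_boot = 10, seed = 3)); b <- runif(1)
  expect_identical(a, b)
  # all p-values above the whole grid: pi0(lambda) is flat, smallest lambda wins
  pd <- rep(0.97, 200)
  ed <- pi0_bootstrap(pd, grid = seq(0, 0.9, 0.1), n_boot = 20, seed = 1)
  expect_identical(ed$tuning$lambda, 0)
  expect_equal(ed$value, 1) # clipped common value
})

test_that("LBE moment order follows the family-size rule with exact breakpoints", {
  expect_identical(pi0_lbe(runif(2))$tuning$m, 1L)
  expect_identical(pi0_lbe(runif(1999))$tuning$m, 1L)
  expect_identical(pi0_lbe(runif(2000))$tuning$m, 2L)
  expect_identical(pi0_lbe(runif(7499))$tuning$m, 2L)
  expect_identical(pi0_lbe(runif(7500))$tuning$m, 3L)
  expect_error(pi0_lbe(0.5), "at least 2")
})

test_that("LBE closed form is exact on designed inputs and clamps p = 1", {
  # -log(1 - p) = 1 for every observation -> estimate exactly 1
  p <- rep(1 - exp(-1), 100)
  expect_equal(pi0_lbe(p)$value, 1, tolerance = 1e-12)
  # half the mass at -log(1-p) = 0.5 transform value
  p2 <- rep(1 - exp(-0.5), 50)
  expect_equal(pi0_lbe(p2)$value, 0.5, tolerance = 1e-12)
  expect_warning(e <- pi0_lbe(c(rep(0.2, 10), 1)), "clamped")
  expect_lte(e$value, 1)
})

test_that("SDPB bound is conservative under the null and detects dense signal", {
  set.seed(8)
  u <- runif(2000)
  expect_gte(pi0_sdpb(u)$value, 0.95) # L-hat ~ 0 under the complete null
  # half the p-values essentially zero: the bound must see at least ~0.4 signal
  p <- c(rep(1e-6, 500), runif(500))
  est <- pi0_sdpb(p)
  expect_lte(est$value, 0.6)
  expect_gte(est$value, 0) # clipping contract
  # asymptotic bounding sequence is a valid fast path with the same shape
  est2 <- pi0_sdpb(p, bounding = "asymptotic")
  expect_lte(est2$value, 0.6)
  expect_identical(pi0_sdpb(u)$tuning$bounding, "calibrated")
})

test_that("all four estimators recover pi0 ~ 1 on uniform p-values", {
  set.seed(17)
  u <- runif(5000)
  expect_equal(pi0_smoothing(u)$value, 1, tolerance = 0.05)
  expect_equal(pi0_bootstrap(u, n_boot = 50, seed = 2)$value, 1, tolerance = 0.05)
  expect_equal(pi0_lbe(u)$value, 1, tolerance = 0.05)
  expect_equal(pi0_sdpb(u)$value, 1, tolerance = 0.05)
})

test_that("modal aggregation reproduces the interval-mode arithmetic", {
  expect_equal(pi0_mode(c(0.80, 0.84, 0.92, 0.61)), 0.82)
  expect_equal(pi0_mode(0.7), 0.7)
  expect_equal(pi0_mode(c(0.10, 0.10, 0.90)), 0.10)
  # tie between bins -> the larger-valued bin wins (conservative)
  expect_equal(pi0_mode(c(0.10, 0.11, 0.90, 0.91)), mean(c(0.90, 0.91)))
  # accepts pi0_estimate objects
  ests <- list(pi0_lbe(rep(1 - exp(-1), 10)),
               pi0_lbe(rep(1 - exp(-1), 20)))
  expect_equal(pi0_mode(ests), 1)
  expect_error(pi0_mode(numeric(0)), "at least one")
})
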