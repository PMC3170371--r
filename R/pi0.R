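clip01 <- function(x) pmin(1, pmax(0, x))

#' Default lambda grid for pi0 estimation
#'
#' The grid `0, 0.05, 0.10, ..., 0.95` used by the smoothing and bootstrap
#' estimators of the proportion of true nulls.
#' @return Numeric vector of 20 lambda values.
#' @export
default_lambda_grid <- function() seq(0, 0.95, by = 0.05)

new_pi0_estimate <- function(value, method, tuning = list()) {
  structure(list(value = clip01(value), method = method, tuning = tuning),
            class = "pi0_estimate")
}

#' @export
print.pi0_estimate <- function(x, ...) {
  cat(sprintf("pi0 estimate (%s): %.4f\n", x$method, x$value))
  invisible(x)
}

#' Raw pi0 estimate at a single lambda
#'
#' The plug-in estimator `#\{p_i > lambda\} / (S * (1 - lambda))` of the
#' proportion of true null hypotheses: p-values above `lambda` are assumed to
#' come mostly from true nulls, whose p-values are uniform, so the count above
#' `lambda` scaled by the uniform mass `1 - lambda` estimates `pi0 * S`. The
#' value is deliberately not clipped to \[0, 1\] here; clipping happens in the
#' estimator-level functions.
#'
#' @param p Numeric vector of p-values.
#' @param lam Tuning threshold in \[0, 1).
#' @return Unclipped estimate (can exceed 1 by sampling noise).
#' @examples
#' pi0_at_lambda(c(0.1, 0.2, 0.6, 0.8), 0.5) # 1
#' @export
pi0_at_lambda <- function(p, lam) {
  p <- as_pvalues(p)
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) ||
      lam < 0 || lam >= 1) {
    stop("lambda must be a single number in [0, 1)", call. = FALSE)
  }
  sum(p > lam) / (length(p) * (1 - lam))
}

check_lambda_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 1L || anyNA(grid) ||
      any(grid < 0 | grid >= 1) || is.unsorted(grid, strictly = TRUE)) {
    stop("lambda grid must be strictly increasing within [0, 1)", call. = FALSE)
  }
  as.numeric(grid)
}

pi0_on_grid <- function(p, grid) {
  sp <- sort(p)
  S <- length(p)
  (S - findInterval(grid, sp)) / (S * (1 - grid))
}

#' Smoothing (spline) estimator of pi0
#'
#' Fits a natural cubic smoothing spline to the curve
#' `(lambda_r, pi0(lambda_r))` over a grid of lambda values and evaluates it
#' at `lambda = 1`. As lambda approaches 1 the plug-in estimate loses bias
#' (only true nulls survive) but gains variance; the spline extrapolates the
#' bias-free limit. By default the spline uses 3 degrees of freedom as in the
#' classic q-value algorithm; `df = NULL` lets the flexibility be chosen by
#' generalized cross-validation.
#'
#' @param p Numeric vector of p-values.
#' @param grid Strictly increasing lambda grid in \[0, 1); at least 4 points.
#' @param df Spline degrees of freedom (default 3), or `NULL` for GCV.
#' @return A `"pi0_estimate"` object (value clipped to \[0, 1\]).
#' @export
pi0_smoothing <- function(p, grid = default_lambda_grid(), df = 3) {
  p <- as_pvalues(p)
  grid <- check_lambda_grid(grid)
  if (length(grid) < 4L) {
    stop("smoothing estimator needs at least 4 lambda grid points", call. = FALSE)
  }
  y <- pi0_on_grid(p, grid)
  fit <- if (is.null(df)) {
    stats::smooth.spline(grid, y)
  } else {
    stats::smooth.spline(grid, y, df = df)
  }
  new_pi0_estimate(stats::predict(fit, x = 1)$y, "smoothing",
                   list(grid = grid, df = if (is.null(df)) fit$df else df))
}

#' Bootstrap estimator of pi0
#'
#' Selects the tuning parameter lambda by minimizing a bootstrap estimate of
#' the mean-squared error of the plug-in pi0 estimator. For each bootstrap
#' resample of the p-values, the plug-in estimate is computed on the grid; the
#' MSE at each lambda is measured around the minimum plug-in estimate over the
#' grid (the least-biased attainable value), and the lambda with smallest
#' bootstrap MSE is chosen (smallest lambda on ties). The returned estimate is
#' the plug-in value of the original data at that lambda.
#'
#' @param p Numeric vector of p-values.
#' @param grid Strictly increasing lambda grid in \[0, 1).
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param seed Optional integer; when given, the resampling is run under a
#'   private RNG state seeded with it (the caller's RNG is untouched) so the
#'   estimate is reproducible.
#' @return A `"pi0_estimate"` object with the chosen lambda in `$tuning`.
#' @export
pi0_bootstrap <- function(p, grid = default_lambda_grid(), n_boot = 100,
                          seed = NULL) {
  p <- as_pvalues(p)
  grid <- check_lambda_grid(grid)
  if (n_boot < 1L) stop("n_boot must be at least 1", call. = FALSE)
  pi0_hat <- pi0_on_grid(p, grid)
  min0 <- min(pi0_hat)
  boot_mse <- function() {
    S <- length(p)
    mse <- numeric(length(grid))
    for (b in seq_len(n_boot)) {
      pb <- p[sample.int(S, S, replace = TRUE)]
      mse <- mse + (pi0_on_grid(pb, grid) - min0)^2
    }
    mse / n_boot
  }
  mse <- if (is.null(seed)) boot_mse() else with_seed(seed, boot_mse())
  lam <- grid[which.min(mse)] # first index = smallest lambda on ties
  new_pi0_estimate(pi0_hat[which.min(mse)], "bootstrap",
                   list(grid = grid, lambda = lam, n_boot = n_boot, seed = seed))
}

#' Location-based estimator (LBE) of pi0
#'
#' Moment estimator built on the transform `-log(1 - p)`, which is Exp(1)
#' distributed for uniform (true-null) p-values: the m-th moment of an Exp(1)
#' variable is `m!`, so `sum((-log(1 - p_i))^m) / (S * m!)` estimates the null
#' fraction. The moment order `m` is set from the family size by the published
#' rule (derived from a variance bound with threshold `l = 0.05^2`): `m = 1`
#' for `2 <= S < 2000`, `m = 2` for `2000 <= S < 7500`, `m = 3` for
#' `S >= 7500`. P-values exactly 1 would make the transform diverge and are
#' clamped at `1 - 1e-8` with a warning.
#'
#' @param p Numeric vector of at least 2 p-values.
#' @return A `"pi0_estimate"` object with `m` in `$tuning`.
#' @export
pi0_lbe <- function(p) {
  p <- as_pvalues(p)
  S <- length(p)
  if (S < 2L) stop("LBE needs at least 2 p-values", call. = FALSE)
  m <- if (S < 2000L) 1L else if (S < 7500L) 2L else 3L
  eps <- 1e-8
  if (any(p > 1 - eps)) {
    warning("p-values at 1 clamped to 1 - 1e-8 for the -log(1-p) transform")
    p <- pmin(p, 1 - eps)
  }
  est <- sum((-log1p(-p))^m) / (S * factorial(m))
  new_pi0_estimate(est, "lbe", list(m = m))
}

# Monte-Carlo calibration of the SDPB bounding sequence beta_{S,alpha}:
# (1-alpha) quantile, under the complete null, of the normalized maximal ECDF
# excess sup_t (ECDF(t) - t) / sqrt(t(1-t)) evaluated at the sample points and
# the default lambda grid (the same evaluation rule the estimator uses).
sdpb_beta <- function(S, alpha, bounding, n_cal = 2000L) {
  if (bounding == "asymptotic") {
    return(sqrt(2 * log(log(S)) / S))
  }
  key <- paste0("sdpb:", S, ":", format(alpha, digits = 15), ":", n_cal)
  if (!is.null(.sgof_cache[[key]])) return(.sgof_cache[[key]])
  grid <- default_lambda_grid()
  grid <- grid[grid > 0 & grid < 1]
  v <- with_seed(20110909 %% .Machine$integer.max, {
    vapply(seq_len(n_cal), function(i) {
      u <- sort(runif(S))
      f_u <- seq_len(S) / S
      stat_u <- (f_u - u) / sqrt(u * (1 - u))
      f_g <- findInterval(grid, u) / S
      stat_g <- (f_g - grid) / sqrt(grid * (1 - grid))
      max(stat_u, stat_g)
    }, numeric(1))
  })
  beta <- as.numeric(stats::quantile(v, 1 - alpha, names = FALSE))
  .sgof_cache[[key]] <- beta
  beta
}

#' Standard-deviation-proportional bounding (SDPB) estimator of pi0
#'
#' Bounds from above the possible contribution of true nulls to the empirical
#' distribution function of the p-values, using the bounding function
#' `beta_{S,alpha} * sqrt(t(1-t))` proportional to the binomial standard
#' deviation of the ECDF. The resulting lower bound on the fraction of false
#' nulls is
#' `L = sup_t (ECDF(t) - t - beta*sqrt(t(1-t))) / (1 - t)` (floored at 0),
#' and the estimate is `pi0 = 1 - L`. With probability at least `1 - alpha`
#' under any configuration, `L` does not exceed the true fraction of false
#' nulls, so the pi0 estimate is conservative (biased upward). The supremum is
#' evaluated at the observed p-values plus the default lambda grid, which
#' suffices because the ECDF is a step function.
#'
#' The bounding sequence `beta_{S,alpha}` is calibrated by Monte Carlo under
#' the complete null (2000 uniform replicates at the given S, fixed internal
#' seed), giving a finite-sample exact-in-distribution level; the asymptotic
#' rate `sqrt(2 log log S / S)` is available as a fast alternative.
#'
#' @param p Numeric vector of p-values.
#' @param alpha Confidence level parameter in (0, 1) (default 0.05).
#' @param bounding `"calibrated"` (Monte-Carlo, default) or `"asymptotic"`.
#' @return A `"pi0_estimate"` object with `beta` in `$tuning`.
#' @export
pi0_sdpb <- function(p, alpha = 0.05, bounding = c("calibrated", "asymptotic")) {
  p <- as_pvalues(p)
  alpha <- check_alpha(alpha)
  bounding <- match.arg(bounding)
  S <- length(p)
  beta <- sdpb_beta(S, alpha, bounding)
  grid <- default_lambda_grid()
  t_eval <- sort(unique(c(p, grid)))
  t_eval <- t_eval[t_eval > 0 & t_eval < 1]
  if (length(t_eval) == 0L) {
    return(new_pi0_estimate(1, "sdpb", list(beta = beta, bounding = bounding)))
  }
  f_hat <- findInterval(t_eval, sort(p)) / S
  l_hat <- max(0, (f_hat - t_eval - beta * sqrt(t_eval * (1 - t_eval))) /
                    (1 - t_eval))
  new_pi0_estimate(1 - l_hat, "sdpb",
                   list(beta = beta, bounding = bounding, alpha = alpha))
}

#' Modal aggregation of several pi0 estimates
#'
#' Groups pi0 estimates into half-open intervals `[k*w, (k+1)*w)` of width `w`
#' anchored at 0 and returns the average of the estimates falling in the most
#' populated interval. When several intervals tie for the largest count, the
#' interval containing the larger values wins (the more conservative choice:
#' a higher pi0 yields higher FDR estimates). This is the rule used to combine
#' the four estimators into a single consensus value.
#'
#' @param estimates Numeric vector of pi0 values in \[0, 1\], or a list of
#'   `"pi0_estimate"` objects.
#' @param bin_width Interval width (default 0.05).
#' @return The aggregated pi0, a single number.
#' @examples
#' pi0_mode(c(0.80, 0.84, 0.92, 0.61)) # 0.82
#' @export
pi0_mode <- function(estimates, bin_width = 0.05) {
  if (is.list(estimates)) {
    estimates <- vapply(estimates, function(e) {
      if (inherits(e, "pi0_estimate")) e$value else as.numeric(e)
    }, numeric(1))
  }
  if (length(estimates) == 0L || anyNA(estimates)) {
    stop("at least one non-missing pi0 estimate is required", call. = FALSE)
  }
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be positive", call. = FALSE)
  }
  bin <- floor(estimates / bin_width)
  counts <- table(bin)
  top <- names(counts)[counts == max(counts)]
  winner <- max(as.numeric(top)) # tie-break toward the larger-valued interval
  mean(estimates[bin == winner])
}

#' All four pi0 estimators plus their modal aggregate
#'
#' Convenience wrapper running the smoothing, bootstrap, LBE and SDPB
#' estimators on the same p-values and aggregating them with [pi0_mode()].
#'
#' @param p Numeric vector of p-values.
#' @param grid Lambda grid for the smoothing and bootstrap estimators.
#' @param n_boot Bootstrap resamples.
#' @param alpha Level for the SDPB bound.
#' @param seed Seed for the bootstrap resampling.
#' @return A list with elements `estimates` (named list of `"pi0_estimate"`
#'   objects) and `mode` (the aggregated value).
#' @export
pi0_all <- function(p, grid = default_lambda_grid(), n_boot = 100,
                    alpha = 0.05, seed = NULL) {
  ests <- list(
    smoothing = pi0_smoothing(p, grid),
    bootstrap = pi0_bootstrap(p, grid, n_boot = n_boot, seed = seed),
    lbe = pi0_lbe(p),
    sdpb = pi0_sdpb(p, alpha = alpha)
  )
  list(estimates = ests, mode = pi0_mode(ests))
}
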