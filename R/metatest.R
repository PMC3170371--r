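# package-local cache for expensive deterministic quantities
# (exact KS critical values, SDPB bounding-sequence calibrations)
.sgof_cache <- new.env(parent = emptyenv())

#' Empirical exceedance proportion of a p-value set
#'
#' Computes `K_gamma`, the proportion of p-values at or below a threshold
#' `gamma` (closed inequality). Under the complete null `E(K_gamma) = gamma`,
#' so `K_gamma - gamma` measures the excess of small p-values over the uniform
#' expectation; this difference drives both SGoF and SGoF+.
#'
#' @param p Numeric vector of p-values (see [as_pvalues()]).
#' @param gamma Threshold in \[0, 1\].
#' @return Proportion of p-values `<= gamma`, a number in \[0, 1\].
#' @examples
#' empirical_exceedance(c(0.01, 0.03, 0.2, 0.7), 0.05) # 0.5
#' @export
empirical_exceedance <- function(p, gamma) {
  p <- as_pvalues(p)
  if (!is.numeric(gamma) || length(gamma) != 1L || is.na(gamma) ||
      gamma < 0 || gamma > 1) {
    stop("gamma must be a single number in [0, 1]", call. = FALSE)
  }
  mean(p <= gamma)
}

#' Select the SGoF+ discriminant threshold gamma0
#'
#' Chooses the rejection-region threshold as the maximizer of
#' `K_gamma - gamma`, the distance between the empirical p-value distribution
#' and the uniform. This is the Youden-index point of the p-value ECDF: the
#' threshold of maximum separation between observed and expected rejections.
#' Candidates are the distinct observed p-values strictly inside (0, 1) (the
#' ECDF only jumps at observed values, and the closed `<=` convention means
#' the supremum of the difference is attained at one of them); ties are broken
#' toward the smallest maximizing threshold, giving the most conservative
#' rejection region.
#'
#' @param p Numeric vector of p-values.
#' @return The selected threshold, or `NA_real_` (with a warning) when every
#'   p-value is exactly 0 or 1 so no valid binomial null exists.
#' @examples
#' select_gamma0(c(0.01, 0.02, 0.9, 0.95)) # 0.02
#' @export
select_gamma0 <- function(p) {
  p <- as_pvalues(p)
  cand <- sort(unique(p))
  cand <- cand[cand > 0 & cand < 1]
  if (length(cand) == 0L) {
    warning("all p-values are exactly 0 or 1; no valid gamma0 candidate")
    return(NA_real_)
  }
  # K_gamma at each candidate via one pass over the sorted sample
  k <- findInterval(cand, sort(p)) / length(p)
  diff <- k - cand
  cand[which.max(diff)] # which.max returns the first (smallest) maximizer
}

# Birnbaum-Tingey exact upper-tail probability of the one-sided
# Kolmogorov-Smirnov statistic D_n^+ = sup_t (ECDF(t) - t) for uniform data:
# P(D_n^+ >= d) = d * sum_{j=0}^{floor(n(1-d))} C(n,j) (d+j/n)^{j-1} (1-d-j/n)^{n-j}
ks_plus_tail <- function(n, d) {
  if (d <= 0) return(1)
  if (d >= 1) return(0)
  j <- 0:floor(n * (1 - d))
  rest <- 1 - d - j / n
  lt <- lchoose(n, j) + (j - 1) * log(d + j / n) +
    ifelse(rest > 0, (n - j) * log(rest), ifelse(n - j == 0, 0, -Inf))
  min(1, d * sum(exp(lt)))
}

#' One-sided Kolmogorov-Smirnov critical value
#'
#' Level-`alpha` critical value for the one-sided KS statistic
#' `sup_t (ECDF(t) - t)` on `S` observations, used by SGoF+ as a guard: no
#' discovery is declared unless the maximal ECDF excess exceeds this value,
#' which restores weak family-wise error control at level `alpha` despite the
#' data-driven choice of threshold. The exact Birnbaum-Tingey distribution is
#' inverted for `S <= 1000`; beyond that the asymptotic form
#' `sqrt(log(1/alpha) / (2 S))` is used.
#'
#' @param alpha Test level in (0, 1).
#' @param S Number of observations (tests), a positive integer.
#' @param exact Logical; force the exact (`TRUE`) or asymptotic (`FALSE`)
#'   computation. Default `NULL` picks exact for `S <= 1000`.
#' @return The critical distance, a number in (0, 1).
#' @examples
#' ks_one_sided_critical(0.05, 100, exact = FALSE) # ~0.1224
#' @export
ks_one_sided_critical <- function(alpha, S, exact = NULL) {
  alpha <- check_alpha(alpha)
  S <- as.integer(S)
  if (is.na(S) || S < 1L) stop("S must be a positive integer", call. = FALSE)
  if (is.null(exact)) exact <- S <= 1000L
  if (!exact) {
    return(sqrt(log(1 / alpha) / (2 * S)))
  }
  key <- paste0("ks:", S, ":", format(alpha, digits = 15))
  if (!is.null(.sgof_cache[[key]])) return(.sgof_cache[[key]])
  val <- stats::uniroot(function(d) ks_plus_tail(S, d) - alpha,
                        lower = 1e-12, upper = 1 - 1e-12, tol = 1e-10)$root
  .sgof_cache[[key]] <- val
  val
}

#' Critical count for the goodness-of-fit metatest
#'
#' Returns `b_alpha(gamma0)`, the critical value of the count of p-values at
#' or below `gamma0` for the metatest of H0: `E(K_gamma0) = gamma0`; the
#' metatest rejects when the observed count is `>= b`. In binomial mode `b` is
#' the 100(1-alpha)% percentile of Binomial(S, gamma0): the smallest integer
#' `k` with CDF(k) >= 1 - alpha. In chi-squared mode `b` is the equivalent
#' count threshold of the one-sided two-cell chi-squared(1) test (reject only
#' for an excess of small p-values), i.e. the smallest integer exceeding
#' `S*gamma0 + z_{1-alpha} * sqrt(S*gamma0*(1-gamma0))`.
#'
#' Because the binomial is discrete, the percentile rule can give a test whose
#' actual size slightly exceeds `alpha`; `conservative = TRUE` instead returns
#' the smallest `k` with `P(X >= k) <= alpha` (one unit larger), guaranteeing
#' size at most `alpha`.
#'
#' @param S Number of tests.
#' @param gamma0 Null proportion, strictly inside (0, 1).
#' @param alpha Metatest level in (0, 1).
#' @param mode `"auto"` (chi-squared for `S >= 10`, binomial otherwise, as in
#'   the classic implementation), `"binomial"`, or `"chi2"`.
#' @param conservative Logical; binomial mode only (see Details).
#' @return Integer critical count.
#' @examples
#' gof_critical_value(10, 0.5, 0.05, mode = "binomial")  # 8
#' gof_critical_value(100, 0.001, 0.05, mode = "binomial") # 1
#' @export
gof_critical_value <- function(S, gamma0, alpha = 0.05,
                               mode = c("auto", "binomial", "chi2"),
                               conservative = FALSE) {
  mode <- match.arg(mode)
  alpha <- check_alpha(alpha)
  S <- as.integer(S)
  if (is.na(S) || S < 1L) stop("S must be a positive integer", call. = FALSE)
  if (!is.numeric(gamma0) || length(gamma0) != 1L || is.na(gamma0) ||
      gamma0 <= 0 || gamma0 >= 1) {
    stop("gamma0 must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (mode == "auto") mode <- if (S >= 10L) "chi2" else "binomial"
  if (mode == "binomial") {
    b <- stats::qbinom(1 - alpha, S, gamma0)
    if (conservative) b <- b + 1L
    return(as.integer(b))
  }
  # one-sided chi2(1): (k - S*g)^2 / (S*g*(1-g)) >= z_{1-alpha}^2 with k > S*g
  z <- stats::qnorm(1 - alpha)
  bound <- S * gamma0 + z * sqrt(S * gamma0 * (1 - gamma0))
  b <- ceiling(bound) # k >= bound; an exactly attained bound counts as rejection
  as.integer(max(b, floor(S * gamma0) + 1))
}

# shared core: run the goodness-of-fit metatest at threshold `gamma` and
# assemble the result object
run_metatest <- function(p, gamma, alpha, gof, conservative, method_label,
                         ks_guard_passed, ks_distance, ks_critical,
                         reject_ties = FALSE, cap = NULL) {
  S <- length(p)
  k_gamma <- as.integer(sum(p <= gamma))
  k_alpha <- as.integer(sum(p <= alpha))
  gof_used <- if (gof == "auto") {
    if (S >= 10L) "chi-squared" else "binomial"
  } else if (gof == "chi2") "chi-squared" else "binomial"
  b <- gof_critical_value(S, gamma, alpha,
                          mode = if (gof_used == "chi-squared") "chi2" else "binomial",
                          conservative = conservative)
  n <- if (ks_guard_passed && k_gamma >= b) k_gamma - b + 1L else 0L
  if (!is.null(cap)) n <- min(n, cap)
  n <- max(n, 0L)
  rejected <- if (n > 0L) order(p)[seq_len(n)] else integer(0)
  if (reject_ties && n > 0L) {
    boundary <- p[rejected[n]]
    rejected <- which(p <= boundary)
    n <- length(rejected)
  }
  structure(list(
    method_label = method_label,
    S = S,
    alpha = alpha,
    gamma0 = gamma,
    k_gamma0 = k_gamma,
    k_alpha = k_alpha,
    critical_value = b,
    gof_test_used = gof_used,
    n_discoveries = as.integer(n),
    rejected_indices = as.integer(rejected),
    ks_guard_passed = ks_guard_passed,
    ks_distance = ks_distance,
    ks_critical = ks_critical
  ), class = "sgof_test")
}

#' SGoF: sequential goodness-of-fit metatest at a fixed threshold
#'
#' Tests whether the observed proportion of p-values at or below `gamma`
#' exceeds its uniform expectation `gamma`, via an exact binomial or one-sided
#' chi-squared goodness-of-fit test at level `alpha`. On rejection, the excess
#' of significants `S*K_gamma - b_alpha(gamma) + 1` smallest p-values are
#' declared discoveries. With the default `gamma = alpha` this is the original
#' SGoF procedure, which controls the family-wise error rate in the weak sense
#' at level `alpha`; no Kolmogorov-Smirnov guard is needed.
#'
#' @param p Numeric vector of p-values.
#' @param alpha Metatest level (default 0.05).
#' @param gamma Fixed significance threshold (default 0.05).
#' @param gof Goodness-of-fit test: `"auto"` (chi-squared when `S >= 10`),
#'   `"binomial"`, or `"chi2"`.
#' @param conservative Passed to [gof_critical_value()].
#' @param reject_ties If `TRUE`, p-values tied with the largest rejected one
#'   are also rejected (off by default; the default rejects exactly the
#'   excess count, breaking ties by input order).
#' @return An object of class `"sgof_test"`: a list with the threshold used
#'   (`gamma0`), counts `k_gamma0` and `k_alpha`, the critical count
#'   `critical_value`, `n_discoveries`, `rejected_indices` (positions in the
#'   input vector of the discoveries, i.e. the smallest p-values), and
#'   bookkeeping fields.
#' @examples
#' p <- c(rep(0.001, 50), rep(0.9, 50))
#' sgof(p)$n_discoveries # 42
#' @seealso [sgof_plus()] for the automatic-threshold version.
#' @export
sgof <- function(p, alpha = 0.05, gamma = alpha,
                 gof = c("auto", "binomial", "chi2"),
                 conservative = FALSE, reject_ties = FALSE) {
  p <- as_pvalues(p)
  alpha <- check_alpha(alpha)
  gof <- match.arg(gof)
  if (gamma <= 0 || gamma >= 1) {
    stop("gamma must lie strictly inside (0, 1)", call. = FALSE)
  }
  run_metatest(p, gamma, alpha, gof, conservative,
               method_label = "SGoF",
               ks_guard_passed = TRUE, # by convention: fixed gamma needs no guard
               ks_distance = sum(p <= gamma) / length(p) - gamma,
               ks_critical = NA_real_,
               reject_ties = reject_ties)
}

#' SGoF+: metatest with automatic threshold and weak-FWER guard
#'
#' Extends [sgof()] by choosing the threshold from the data:
#' `gamma0 = argmax_gamma (K_gamma - gamma)`, the point of maximum distance
#' between the empirical p-value distribution and the uniform (see
#' [select_gamma0()]). Because the data-driven choice alone would inflate the
#' family-wise error rate above `alpha`, a guard is applied first: no effect
#' is declared unless `K_gamma0 - gamma0` reaches the level-`alpha` critical
#' value of the one-sided Kolmogorov-Smirnov test ([ks_one_sided_critical()]).
#' The maximized difference is exactly the one-sided KS statistic, so the
#' guard restores weak FWER control at `100*alpha`%. When the guard and the
#' goodness-of-fit metatest both reject, the
#' `min(S*K_gamma0 - b_alpha(gamma0) + 1, S*K_alpha)` smallest p-values are
#' declared discoveries — the cap by `S*K_alpha` excludes p-values above
#' `alpha` from ever being called, since `gamma0` may exceed `alpha`.
#'
#' @inheritParams sgof
#' @param ks_exact Passed as `exact` to [ks_one_sided_critical()].
#' @return An object of class `"sgof_test"`; see [sgof()]. Here
#'   `ks_guard_passed` reports the guard outcome and `gamma0` the selected
#'   threshold.
#' @examples
#' p <- c(rep(0.001, 50), rep(0.9, 50))
#' r <- sgof_plus(p)
#' r$gamma0          # 0.001
#' r$n_discoveries   # 50
#' @export
sgof_plus <- function(p, alpha = 0.05,
                      gof = c("auto", "binomial", "chi2"),
                      conservative = FALSE, reject_ties = FALSE,
                      ks_exact = NULL) {
  p <- as_pvalues(p)
  alpha <- check_alpha(alpha)
  gof <- match.arg(gof)
  S <- length(p)
  gamma0 <- select_gamma0(p)
  ks_crit <- ks_one_sided_critical(alpha, S, exact = ks_exact)
  if (is.na(gamma0)) {
    # degenerate input (all p exactly 0 or 1): no valid binomial null
    return(run_metatest(p, alpha, alpha, gof, conservative,
                        method_label = "SGoF+",
                        ks_guard_passed = FALSE,
                        ks_distance = NA_real_, ks_critical = ks_crit))
  }
  dist <- sum(p <= gamma0) / S - gamma0
  guard <- dist >= ks_crit
  run_metatest(p, gamma0, alpha, gof, conservative,
               method_label = "SGoF+",
               ks_guard_passed = guard,
               ks_distance = dist, ks_critical = ks_crit,
               reject_ties = reject_ties,
               cap = as.integer(sum(p <= alpha)))
}

#' @export
print.sgof_test <- function(x, ...) {
  cat(sprintf("%s metatest (%s GoF test)\n", x$method_label, x$gof_test_used))
  cat(sprintf("  S = %d tests, alpha = %g\n", x$S, x$alpha))
  cat(sprintf("  threshold gamma0 = %g  (count <= gamma0: %d, critical: %d)\n",
              x$gamma0, x$k_gamma0, x$critical_value))
  if (x$method_label == "SGoF+") {
    cat(sprintf("  KS guard: distance %.4f vs critical %.4f -> %s\n",
                x$ks_distance, x$ks_critical,
                if (x$ks_guard_passed) "passed" else "failed (no discoveries)"))
  }
  cat(sprintf("  discoveries: %d\n", x$n_discoveries))
  invisible(x)
}
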