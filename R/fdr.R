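#' Estimated positive false discovery rate at a threshold
#'
#' Estimates the pFDR incurred when every test with `p_i <= threshold` is
#' called significant:
#' `epFDR(p) = min(1, pi0 * S * p / (R(p) * C))`,
#' where `R(p)` is the number of p-values at or below the threshold and `C`
#' accounts for conditioning on at least one rejection. The robust variant
#' uses `C = 1 - (1 - p)^S`, the probability under the complete null that at
#' least one of `S` uniform p-values falls below `p`; it should be preferred
#' when sample sizes are small or effects weak. The standard variant sets
#' `C = 1`.
#'
#' @param p Numeric vector of p-values.
#' @param threshold Rejection threshold in (0, 1\]; at least one p-value must
#'   lie at or below it (pFDR conditions on a rejection having been made).
#' @param pi0 Proportion of true nulls in \[0, 1\] (a number or a
#'   `"pi0_estimate"`).
#' @param robust Logical; robust (`TRUE`, default) or standard variant.
#' @return The estimated pFDR, clipped to \[0, 1\].
#' @examples
#' epfdr(runif(100), threshold = 0.5, pi0 = 1)
#' @export
epfdr <- function(p, threshold, pi0 = 1, robust = TRUE) {
  p <- as_pvalues(p)
  if (inherits(pi0, "pi0_estimate")) pi0 <- pi0$value
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single number in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(pi0) || length(pi0) != 1L || is.na(pi0) ||
      pi0 < 0 || pi0 > 1) {
    stop("pi0 must be a single number in [0, 1]", call. = FALSE)
  }
  S <- length(p)
  r <- sum(p <= threshold)
  if (r == 0L) {
    stop("no p-value at or below the threshold: pFDR is undefined without a rejection",
         call. = FALSE)
  }
  cc <- if (robust) 1 - (1 - threshold)^S else 1
  min(1, pi0 * S * threshold / (r * cc))
}

#' Per-test q-values from the epFDR curve
#'
#' The q-value of a test is the smallest estimated pFDR over all rejection
#' regions that include it: epFDR is evaluated at each observed p-value (the
#' thresholds where the rejection count changes) and the q-value is the
#' running minimum of epFDR from the largest p-value downwards, mapped back to
#' the input order.
#'
#' @inheritParams epfdr
#' @return A data frame of class `"qvalue_table"` in input order with columns
#'   `index`, `p`, `epfdr` (the estimate at that test's own threshold) and
#'   `qvalue`; attributes `pi0` and `robust` record the calibration.
#' @examples
#' qv <- qvalues(c(0.001, 0.01, 0.2, 0.8), pi0 = 1)
#' qv$qvalue
#' @export
qvalues <- function(p, pi0 = 1, robust = TRUE) {
  p <- as_pvalues(p)
  if (inherits(pi0, "pi0_estimate")) pi0 <- pi0$value
  S <- length(p)
  ord <- order(p)
  ps <- p[ord]
  r <- findInterval(ps, ps) # number of p-values <= each sorted threshold
  cc <- if (robust) 1 - (1 - ps)^S else rep(1, S)
  # threshold 0 would condition on an impossible rejection; a zero p-value
  # contributes epFDR 0 (its rejection region contains no null mass)
  ep <- ifelse(ps > 0, pmin(1, pi0 * S * ps / (r * cc)), 0)
  q <- rev(cummin(rev(ep)))
  out <- data.frame(index = seq_len(S), p = p,
                    epfdr = numeric(S), qvalue = numeric(S))
  out$epfdr[ord] <- ep
  out$qvalue[ord] <- q
  attr(out, "pi0") <- pi0
  attr(out, "robust") <- robust
  class(out) <- c("qvalue_table", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: rejects the largest `k` tests with
#' `p_(k) <= k * alpha / S`. Adjusted p-values come from the monotone step-up
#' transform (via [stats::p.adjust()]); the rejection set is exactly the set
#' of tests whose adjusted p-value is at most `alpha`.
#'
#' @param p Numeric vector of p-values.
#' @param alpha Target FDR level in (0, 1).
#' @return List with `adjusted` (adjusted p-values, input order),
#'   `rejected_indices`, `n_discoveries`, and `method = "BH"`.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  p <- as_pvalues(p)
  alpha <- check_alpha(alpha)
  adj <- stats::p.adjust(p, method = "BH")
  rej <- which(adj <= alpha)
  list(method = "BH", alpha = alpha, adjusted = adj,
       rejected_indices = rej, n_discoveries = length(rej))
}

#' Holm (sequential Bonferroni) adjustment
#'
#' Step-down strong family-wise error rate control: rejects sorted p-values
#' while `p_(i) <= alpha / (S - i + 1)`, stopping at the first failure.
#' Adjusted p-values via [stats::p.adjust()]; the rejection set is the set of
#' tests with adjusted p-value at most `alpha`.
#'
#' @param p Numeric vector of p-values.
#' @param alpha FWER level in (0, 1).
#' @return List with `adjusted`, `rejected_indices`, `n_discoveries`, and
#'   `method = "Holm"`.
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  p <- as_pvalues(p)
  alpha <- check_alpha(alpha)
  adj <- stats::p.adjust(p, method = "holm")
  rej <- which(adj <= alpha)
  list(method = "Holm", alpha = alpha, adjusted = adj,
       rejected_indices = rej, n_discoveries = length(rej))
}
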