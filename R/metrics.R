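#' Confusion counts for one replicate
#'
#' Crosses a rejection set against the truth labels of a simulated family.
#'
#' @param rejected Integer vector of rejected test indices (may be empty).
#' @param effect Logical vector of truth labels over all tests (`TRUE` =
#'   the test carries a true effect).
#' @return Named integer vector with elements `tp`, `fp`, `tn`, `fn`.
#' @examples
#' replicate_confusion(c(1, 2), c(FALSE, TRUE, TRUE))
#' @export
replicate_confusion <- function(rejected, effect) {
  if (!is.logical(effect) || anyNA(effect)) {
    stop("effect must be a logical vector without NA", call. = FALSE)
  }
  if (length(rejected) > 0 &&
      (any(rejected < 1) || any(rejected > length(effect)))) {
    stop("rejected indices outside 1..length(effect)", call. = FALSE)
  }
  rej <- logical(length(effect))
  rej[rejected] <- TRUE
  c(tp = sum(rej & effect), fp = sum(rej & !effect),
    tn = sum(!rej & !effect), fn = sum(!rej & effect))
}

#' Signed bias of an estimated pFDR
#'
#' Difference `estimated - observed`; positive values mean the estimator is
#' conservative (overstates the false discovery rate actually committed).
#'
#' @param estimated Estimated pFDR(s) in \[0, 1\].
#' @param observed Observed pFDR(s) in \[0, 1\].
#' @return Signed difference(s).
#' @export
epfdr_bias <- function(estimated, observed) {
  stopifnot(all(estimated >= 0 & estimated <= 1, na.rm = TRUE),
            all(observed >= 0 & observed <= 1, na.rm = TRUE))
  estimated - observed
}

#' Aggregate per-replicate confusions into scenario metrics
#'
#' Computes the evaluation quantities of the simulation study for each
#' method:
#' * power (true positive rate): mean over replicates of `TP / (TP + FN)`,
#'   restricted to replicates where effects are present (`NA` otherwise);
#' * FPR: mean of `FP / (FP + TN)` over replicates with nulls present;
#' * pFDR: mean false discovery proportion `FP / (TP + FP)` restricted to
#'   replicates with at least one discovery (`NA` when no replicate
#'   discovers — the conditional quantity is then undefined, not 0);
#' * FWER: fraction of replicates with at least one false discovery;
#' * power/pFDR ratio (`NA` when pFDR is 0 or undefined);
#' * mean estimated pFDR over discovering replicates and its bias
#'   (estimate minus observed pFDR), when per-replicate epFDR values are
#'   supplied.
#' Monte-Carlo standard errors accompany power, FPR, pFDR and FWER.
#'
#' @param conf Data frame with one row per (method, replicate): columns
#'   `method`, `tp`, `fp`, `tn`, `fn`, and optionally `epfdr` (the estimated
#'   pFDR at that replicate's rejection threshold, `NA` when the method made
#'   no discovery).
#' @return Data frame of class `"scenario_metrics"`, one row per method.
#' @export
aggregate_metrics <- function(conf) {
  stopifnot(is.data.frame(conf),
            all(c("method", "tp", "fp", "tn", "fn") %in% names(conf)))
  if (nrow(conf) == 0L) stop("at least one replicate is required", call. = FALSE)
  has_ep <- "epfdr" %in% names(conf)
  rows <- lapply(split(conf, conf$method), function(d) {
    n_rep <- nrow(d)
    eff_present <- (d$tp + d$fn) > 0
    tpr <- ifelse(eff_present, d$tp / (d$tp + d$fn), NA_real_)
    null_present <- (d$fp + d$tn) > 0
    fpr <- ifelse(null_present, d$fp / (d$fp + d$tn), NA_real_)
    disc <- (d$tp + d$fp) > 0
    fdp <- ifelse(disc, d$fp / (d$tp + d$fp), NA_real_)
    power <- if (any(eff_present)) mean(tpr[eff_present]) else NA_real_
    fpr_m <- if (any(null_present)) mean(fpr[null_present]) else NA_real_
    pfdr <- if (any(disc)) mean(fdp[disc]) else NA_real_
    fwer <- mean(d$fp >= 1)
    ratio <- if (!is.na(pfdr) && pfdr > 0 && !is.na(power)) power / pfdr else NA_real_
    ep_mean <- ep_bias <- NA_real_
    if (has_ep && any(disc & !is.na(d$epfdr))) {
      ep_mean <- mean(d$epfdr[disc], na.rm = TRUE)
      if (!is.na(pfdr)) ep_bias <- epfdr_bias(ep_mean, pfdr)
    }
    mc_se <- function(v) if (sum(!is.na(v)) > 1) {
      stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
    } else NA_real_
    data.frame(
      method = d$method[1], n_replicates = n_rep,
      n_discovering = sum(disc),
      power = power, se_power = mc_se(tpr),
      fpr = fpr_m, se_fpr = mc_se(fpr),
      pfdr = pfdr, se_pfdr = mc_se(fdp),
      fwer = fwer, se_fwer = sqrt(fwer * (1 - fwer) / n_rep),
      power_pfdr_ratio = ratio,
      epfdr = ep_mean, epfdr_bias = ep_bias,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("scenario_metrics", "data.frame")
  out
}

apply_method <- function(method, p, alpha, gamma) {
  switch(method,
    "sgof" = sgof(p, alpha = alpha, gamma = gamma)$rejected_indices,
    "sgof+" = sgof_plus(p, alpha = alpha)$rejected_indices,
    "bh" = bh_adjust(p, alpha = alpha)$rejected_indices,
    "holm" = holm_adjust(p, alpha = alpha)$rejected_indices,
    stop("unknown method '", method, "'", call. = FALSE))
}

#' Run a full simulation study for several adjustment methods
#'
#' Generates `scenario$n_replicates` families with [generate_family()],
#' applies each requested multiple-testing method to every family, records
#' confusion counts, and optionally estimates the pFDR committed by each
#' method on each replicate (epFDR at the method's rejection threshold — the
#' largest rejected p-value — with pi0 re-estimated per replicate).
#'
#' @param scenario A [simulation_scenario()].
#' @param methods Character vector among `"sgof"`, `"sgof+"`, `"bh"`,
#'   `"holm"`.
#' @param gamma Fixed threshold for SGoF (default: the scenario alpha).
#' @param estimate_pfdr Logical; also compute per-replicate epFDR.
#' @param pi0_method Estimator for the per-replicate pi0 when
#'   `estimate_pfdr = TRUE`: `"smoothing"`, `"bootstrap"`, `"lbe"`, `"sdpb"`,
#'   or `"fixed"` (use `pi0_fixed`).
#' @param pi0_fixed Fixed pi0 when `pi0_method = "fixed"`.
#' @param robust Robust (`TRUE`) or standard epFDR variant.
#' @return List with `replicates` (per-(method, replicate) data frame of
#'   confusion counts and epFDR) and `metrics` (the [aggregate_metrics()]
#'   summary).
#' @export
run_simulation_study <- function(scenario,
                                 methods = c("sgof", "sgof+", "bh", "holm"),
                                 gamma = scenario$alpha,
                                 estimate_pfdr = FALSE,
                                 pi0_method = c("smoothing", "bootstrap",
                                                "lbe", "sdpb", "fixed"),
                                 pi0_fixed = 1, robust = TRUE) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  methods <- match.arg(methods, several.ok = TRUE)
  pi0_method <- match.arg(pi0_method)
  recs <- vector("list", scenario$n_replicates * length(methods))
  k <- 0L
  for (r in seq_len(scenario$n_replicates)) {
    fam <- generate_family(scenario, r)
    pi0_r <- if (!estimate_pfdr) NA_real_ else switch(pi0_method,
      smoothing = pi0_smoothing(fam$p)$value,
      bootstrap = pi0_bootstrap(fam$p, seed = replicate_seed(scenario$seed + 1L, r))$value,
      lbe = pi0_lbe(fam$p)$value,
      sdpb = pi0_sdpb(fam$p)$value,
      fixed = pi0_fixed)
    for (m in methods) {
      rej <- apply_method(m, fam$p, scenario$alpha, gamma)
      cf <- replicate_confusion(rej, fam$effect)
      ep <- NA_real_
      if (estimate_pfdr && length(rej) > 0) {
        ep <- epfdr(fam$p, threshold = max(fam$p[rej]), pi0 = pi0_r,
                    robust = robust)
      }
      k <- k + 1L
      recs[[k]] <- data.frame(method = m, replicate = r,
                              tp = cf[["tp"]], fp = cf[["fp"]],
                              tn = cf[["tn"]], fn = cf[["fn"]],
                              epfdr = ep, stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, recs)
  list(replicates = reps, metrics = aggregate_metrics(reps))
}
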