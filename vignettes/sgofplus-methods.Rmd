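---
title: "Sequential goodness-of-fit multiple testing: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential goodness-of-fit multiple testing: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgofplus)
```

## The problem and the model

High-throughput experiments test thousands of hypotheses at once. Strong
FWER control (Holm) and FDR control (Benjamini–Hochberg) pay for their
guarantees with power: as the number of tests `S` grows, their per-test
thresholds shrink, and with small sample sizes and weak effects they may
reject nothing at all. The sequential goodness-of-fit idea inverts the
question: rather than asking *which* tests are significant, it first asks
whether the *collection* of p-values deviates from what `S` true nulls
would produce, and if so, how many effects that deviation supports.

Under the complete null the p-values are i.i.d. Uniform(0, 1), so the
proportion `K_γ` of p-values at or below any threshold `γ` has expectation
`γ` and `S·K_γ ~ Binomial(S, γ)`. The metatest rejects
`H0: E(K_γ) = γ` against an excess of small p-values at level `α`, and on
rejection declares the excess of significants `N = S·K_γ − b_α(γ) + 1`
smallest p-values to be effects, where `b_α(γ)` is the critical count.
Because the binomial variance grows only as `√S` while a fixed fraction of
effects shifts the count linearly in `S`, power *increases* with the number
of tests — the property that motivates the method.

`sgof()` fixes `γ = α` (the original procedure). `sgof_plus()` selects
`γ₀ = argmax_γ (K_γ − γ)`, the threshold of maximum separation between the
empirical and uniform distributions — the Youden index of the p-value ECDF,
i.e. the ROC-optimal operating point for discriminating effect-bearing from
null tests. Two safeguards accompany the automatic choice:

* the excess is capped at `S·K_α`, so p-values above `α` are never declared
  (with `γ₀ > α` the uncapped excess could reach into them);
* a one-sided Kolmogorov–Smirnov guard: since
  `max_γ (K_γ − γ) = sup_t (ECDF(t) − t)` is exactly the one-sided KS
  statistic `D⁺_S`, requiring `K_γ₀ − γ₀ >= ks_α` before declaring anything
  restores weak FWER control at level `α`, which the data-driven `γ₀` alone
  would inflate.

Key assumption: independence (or at most weak, local dependence) of the
p-values. Strong dependence distorts the null distribution of both the
binomial count and `D⁺_S`, and the guard's level is no longer `α`; see
*Limitations*.

## Conventions that the paper trail leaves open

Several small conventions had to be fixed; each is a deliberate choice, made
once:

* **Closed inequality.** `K_γ = #{p_i <= γ}/S`. The ECDF jumps exactly at
  observed p-values, so with the closed convention the supremum of
  `K_γ − γ` is attained at an observed value and the argmax is
  well-defined. Consequently the candidate set for `γ₀` is the distinct
  observed p-values strictly inside (0, 1); endpoints are excluded because
  Binomial(S, 0) and Binomial(S, 1) admit no one-sided test. If every
  p-value is exactly 0 or 1 the procedure warns and declares nothing.
* **Tie-break for `γ₀`:** the smallest maximizer, giving the most
  conservative rejection region.
* **Percentile rule for `b_α`.** The default is the smallest integer `k`
  with `P(Binomial(S, γ₀) <= k) >= 1 − α`. For a discrete distribution this
  rule's actual one-sided size can slightly exceed `α`;
  `conservative = TRUE` uses the smallest `k` with `P(X >= k) <= α` (one
  unit larger), guaranteeing size at most `α`.
* **χ² mode.** For `S >= 10` the default goodness-of-fit test is the
  two-cell χ²₁ statistic made one-sided by rejecting only for an excess of
  small p-values. A one-sided test at level `α` corresponds to the normal
  deviate `z_{1−α}`, so the equivalent count threshold is the smallest
  integer at or above `S·γ₀ + z_{1−α}·√(S·γ₀(1−γ₀))`. (Using the two-sided
  χ² critical value `qchisq(1−α, 1)` would give a one-sided size of `α/2`,
  i.e. a different level than requested.) At `S = 100, γ = 0.05, α = 0.05`
  both modes give `b = 9`.
* **KS critical value.** Exact inversion of the Birnbaum–Tingey one-sided
  distribution for `S <= 1000` (cached per `(S, α)`), the asymptotic
  `√(ln(1/α)/(2S))` beyond. Exactness matters at desk scale: at `S = 100`
  the exact value is 0.1207 versus 0.1224 asymptotic.
* **Ties at the rejection boundary** are broken by input order (stable);
  `reject_ties = TRUE` optionally extends the rejection to all p-values
  equal to the boundary one.

## Estimating the proportion of true nulls

All q-value machinery needs `π₀`, the fraction of tests whose null is true.
Four estimators are provided; all clip the final value into [0, 1] (the
plug-in `pi0_at_lambda()` is deliberately left unclipped so the estimators
see the raw statistic).

* **Smoothing** (`pi0_smoothing`): natural cubic smoothing spline through
  `(λ_r, π̂₀(λ_r))` on the default grid `0, 0.05, …, 0.95`, evaluated at
  `λ = 1`. Default `df = 3` as in the classic q-value algorithm; `df =
  NULL` selects flexibility by generalized cross-validation, honouring that
  the degrees of freedom need not be 3.
* **Bootstrap** (`pi0_bootstrap`): chooses `λ` minimizing the bootstrap MSE
  of `π̂₀(λ)` around the plug-in minimum over the grid; smallest `λ` on
  ties. Reproducible under a user seed via a private RNG state.
* **LBE** (`pi0_lbe`): moment estimator `Σ(−ln(1−p_i))^m / (S·m!)`; for
  uniform p-values `−ln(1−P) ~ Exp(1)` whose m-th moment is `m!`. The
  moment order follows the published family-size rule (`m = 1` for
  `S < 2000`, `m = 2` for `2000 <= S < 7500`, `m = 3` beyond, derived from
  a variance-bound threshold of `0.05²`); the printed breakpoints are taken
  as normative. P-values exactly 1 are clamped at `1 − 10⁻⁸` with a
  warning.
* **SDPB** (`pi0_sdpb`): bounds the maximal null contribution to the ECDF
  with the bounding function `β_{S,α}·√(t(1−t))`, yielding the lower bound
  `L = sup_t (ECDF(t) − t − β√(t(1−t)))/(1−t)` on the fraction of false
  nulls and `π̂₀ = 1 − L`. The bounding sequence is calibrated by Monte
  Carlo under the complete null — 2000 uniform replicates at the observed
  `S`, level `α`, a fixed internal seed, cached per `(S, α)` — because the
  finite-sample distribution of the normalized ECDF excess is heavy near
  `t → 0` and the asymptotic rate `√(2 ln ln S / S)` is optimistic at desk
  scale; the asymptotic rate remains available as a fast option. The
  supremum is evaluated at the observed p-values plus the default λ grid,
  sufficient since the ECDF is a step function. By construction
  `P(L > true fraction of false nulls) <= α`, so the estimator errs upward
  (conservative for FDR purposes).
* **Modal aggregate** (`pi0_mode`): estimates binned into half-open
  intervals `[k·w, (k+1)·w)`, `w = 0.05` by default, anchored at 0; the
  average of the most populated bin is returned. Ties go to the bin with
  larger values — again the conservative direction.

## pFDR, q-values and baselines

`epfdr()` implements `min(1, π₀·S·p / (R(p)·C))` at a threshold `p`, with
`R(p)` the rejection count and `C = 1 − (1−p)^S` (robust; the probability
that *any* of `S` null p-values falls below `p`) or `C = 1` (standard).
The robust variant conditions on at least one rejection and is preferred
with small samples and weak effects; it always dominates the standard one.
A threshold with no rejections is an error by design — pFDR is a
conditional quantity. Thresholds are meaningful only at observed p-values
(where `R` jumps); `qvalues()` evaluates epFDR at each observed value and
takes the running minimum from the largest p-value down, so q-values are
monotone in p and never exceed the test's own epFDR. Estimates are clipped
at 1; an estimated rate above 1 carries no extra information. A p-value of
exactly 0 is assigned epFDR 0 (its rejection region contains no null mass).

BH and Holm are delegated to `stats::p.adjust`; the rejection set at level
`α` is exactly the set of tests with adjusted p-value at or below `α`,
which reproduces the step-up and step-down rules.

## The simulation engine

`generate_family()` emulates the canonical weak-effect design: `S`
one-sample two-tailed t-tests of H0: mean 0, each on `n` draws from N(0, 1)
for nulls and N(x, 1) for effects, with `x = 0.36` by default — the effect
size at which a single 5%-level test has power about 0.10 under asymptotic
conditions; at `n = 5, 10, 20, 100` the exact noncentral-t powers are 0.10,
0.18, 0.33, 0.95. P-values come from the regularized incomplete beta
identity `p = I_{df/(df+t²)}(df/2, 1/2)`, algebraically identical to the
two-tailed t tail probability. The effect count per family is fixed at
`round(S · effect_fraction)` — a deterministic composition matching a
fixed-percentage design, not Bernoulli thinning — and truth labels are
returned so confusion counts are exact. Per-replicate reproducibility uses
a counter-derived seed (root seed and replicate index mixed into one
integer below 2³¹) inside a private RNG state: replicate `r` can be
regenerated without generating `1..r−1`, and library calls never perturb
the caller's RNG.

What the generator does *not* emulate: dependence between tests, heavy
tails or variance heterogeneity, composite alternatives with varying effect
sizes. Passing tests therefore demonstrate correctness of the procedures
under independence and homogeneous weak effects, not robustness to
correlated real data.

`run_simulation_study()` applies any of SGoF, SGoF+, BH and Holm to every
replicate and aggregates: power is the mean per-replicate TPR (per-replicate
averaging, the natural reading when replicates are equally sized); pFDR is
the mean false-discovery proportion *restricted to replicates with at least
one discovery* and is reported as missing — not 0 — when no replicate
discovers; FWER is the fraction of replicates with a false discovery;
power/pFDR summarizes the trade-off. Monte-Carlo standard errors accompany
each aggregate. Optionally the pFDR each method commits is also *estimated*
per replicate (epFDR at the method's threshold, the largest rejected
p-value, with `π₀` re-estimated per replicate by a chosen method), so
estimation bias `epFDR − pFDR` can be measured against the simulation
truth.

## Problem sizes used by the test suite

The suite exercises the same study design at sizes chosen to keep a full
run in tens of seconds: 1,000 null replicates of `S = 1000` for the weak
FWER check; 200 replicates at `S = 1000, n = 20` across effect fractions
5–80% for the power/pFDR/bias trends; `10⁵` replicate tests per sample size
for the power-grid cross-check; 20 replicate families for the π₀ recovery
band (single-family estimates fluctuate ~±0.04 around the truth, so the
band is asserted on the estimator's mean). Oracle-equivalence checks
(binomial percentile, `γ₀` selection, q-values) run against brute-force
enumerations on thousands of small random instances.

## Known limitations

* Everything assumes (weak) independence. Under strong dependence the
  KS guard's level and the binomial null both fail; combining the metatest
  with the more conservative BH, or an empirical-null recalibration, would
  be the way forward — neither is implemented here.
* The epFDR estimator is accurate for the metatest methods at moderate and
  high effect fractions, but at the lowest fractions it splits
  systematically around the truth: it overestimates at SGoF's smaller
  threshold and underestimates at SGoF+'s larger one (the test suite
  measures about ±0.06–0.07 at 5% effects, `n = 20`, `S = 1000`), and for
  BH/Holm the robust conditioning factor makes it grossly conservative when
  discoveries are rare.
* `γ₀` is searched over all distinct observed p-values; with heavy ties the
  stable tie-break makes results deterministic but the selected threshold
  can sit on a large tie block — the `reject_ties` option exists for users
  who prefer to treat tied p-values symmetrically.
* The SDPB calibration costs a few seconds at `S = 10⁴` (cached within a
  session); the asymptotic option trades that cost for a looser bound.
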