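---
title: "Methods: symptom networks from two-wave panel data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: symptom networks from two-wave panel data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(panelsym)
```

## The problem

Two-wave questionnaire panels — here, nine bedtime-procrastination items
(Likert 1–5) and eleven adolescent depression items (0–3), measured 18
months apart in a school cohort split by sex — carry three distinct kinds
of symptom-level structure:

* **between-person**: adolescents who chronically procrastinate at bedtime
  also tend to report chronically higher depressive symptoms;
* **temporal (within-person)**: an elevation of one symptom at wave 1
  predicts deviations of other symptoms at wave 2 within the same person;
* **contemporaneous (within-person)**: same-wave co-fluctuation left over
  after temporal prediction.

`panelsym` estimates all three as networks over the 20 items, quantifies
which nodes matter (strength, expected influence, in/out expected
influence), attaches bootstrap stability evidence, and compares groups by
permutation. This vignette records the modelling choices, their defaults,
and what the tests do and do not establish.

## Models and estimators

### Cross-sectional / contemporaneous GGM

Items are standardized and a sparse precision matrix `K` maximizes the
penalized Gaussian log-likelihood `log det K − tr(SK) − λΣ_{i≠j}|K_ij|`
(off-diagonals only; block coordinate descent in compiled code, tolerance
1e-5 on the maximum parameter change, 1000-sweep cap, non-convergence is an
error). Edge weights are partial correlations
`w_ij = −K_ij / sqrt(K_ii K_jj)`. The penalty is chosen on a 100-point
log-spaced path from `λ_max` (the largest absolute off-diagonal
correlation, which forces an empty graph) down to `λ_max/100`, minimizing
`EBIC = −n(log det K − tr SK) + E log n + 4Eγ log p` with `γ = 0.5`.
The path settings, `γ`, and the use of Pearson correlations on
integer-scored items are conventions of the applied literature rather than
identities; `γ` and the path are arguments, and treating short ordinal
scales as continuous attenuates edge magnitudes somewhat (see the test
suite's recovery margins).

### Cross-lagged panel network

Each wave-2 item, standardized with wave-specific means/SDs so
coefficients are comparable across nodes, is lasso-regressed on all
standardized wave-1 items. The self-lag is *included* in each regression —
cross-lagged coefficients are adjusted for autoregression — but reported
separately (`auto`) and zeroed on the network diagonal, because self-lags
dominate the display and the interest is between-symptom prediction.
Centralities are row sums (out expected influence: how much a node
predicts the rest) and column sums (in expected influence: how much it is
predicted).

**Penalty selection.** The package defaults to EBIC over the per-node
path. Ten-fold cross-validation minimizing squared error is available
(`selection = "cv"`), but measured on sparse null data (no temporal
effects, n = 2000, p = 10) CV-min leaves only about 78% of cross-lagged
coefficients at zero, whereas EBIC leaves ~99.6%; a method advertised as
"setting small coefficients to zero" should actually do so under the null,
so EBIC is the default. Note that *any* n-dependent selection rule (CV
folds, the `log n` term in EBIC) makes the fitted network change when the
dataset is duplicated row-for-row; only the fixed-penalty coefficients are
duplication-invariant, and the tests assert exactly that.

### Between/within decomposition (two waves)

With waves `y_1, y_2`, person means `m = (y_1 + y_2)/2` and half-differences
`d = (y_2 − y_1)/2` decompose the panel. Three estimators, all
"non-regularized": estimate, then prune entries whose test exceeds `α`
(default 0.01; Fisher z with effective sample size `n − p − 1` for partial
correlations, OLS t-tests for temporal coefficients).

* **Between.** `cov(m)` contains half the within-person variance; by
  default the covariance of the half-differences is subtracted
  (`cov(m) − cov(d)`), which under a weak temporal process targets the
  between-person covariance unbiasedly (exact when `B = 0`). Eigenvalues
  are floored before inversion; a ridge fallback is exposed.
* **Temporal.** With exactly two waves, deviations at the waves are exact
  negatives, so a node's own lag is a *perfect* predictor of its outcome
  and the textbook regression is degenerate. The own lag is therefore
  excluded (structural zero diagonal), and what the "temporal" network
  estimates is the sign-flipped deviation regression — a functional of
  `cov(d)`, not the generating lag matrix `B`. This is an honest
  limitation of two-wave data, not of the implementation; the recovery
  tests compare the estimator against the same functional evaluated on the
  known simulation truth (`tests/testthat/helper-oracles.R`,
  `pop_twowave()`).
* **Contemporaneous.** Partial correlations among the deviations
  (equivalently, correlations of the residuals of each pair after
  regressing on the remaining items), pruned the same way. When `B = 0`
  these coincide exactly with the within-person contemporaneous partial
  correlations `−K_w,ij/sqrt(K_w,ii K_w,jj)`; with temporal structure they
  are contaminated by it — again a two-wave identification limit, stated
  rather than hidden. A cross-sectional GGM is available as the alternative
  reading (`analysis_config(contemporaneous = "ggm")`).

Full maximum-likelihood panel-GVAR with model search is out of scope by
design; the estimand (pruned partial associations at the two levels) is
preserved.

### Group comparison

`S = |Σ|w^A| − Σ|w^B||` and `M = max_ij |w^A_ij − w^B_ij|` are compared
with their distributions under label permutation (group sizes preserved,
identical estimator and hyperparameters inside the loop). P-values use the
add-one rule, so they are never exactly zero and the test remains valid at
finite permutation counts. Per-edge permutation p-values are Holm-adjusted
by default (an unadjusted option exists for parity with software that
reports raw edge tests).

### Stability

Edge CIs: nonparametric bootstrap over subjects, 2.5/97.5 percentiles,
failed replicates retried (more than 5% failures aborts). Edge-difference
tests: percentile interval of the per-replicate difference. Centrality
stability: case-drop bootstrap over drop proportions 0.1–0.7; the CS
coefficient is the largest drop proportion at which ≥ 95% of subsample
centralities correlate ≥ 0.7 (Spearman, robust to the centralities' scale;
Pearson optional) with the full-sample values. 0.7/95% is the field's
standard convention behind the "CS ≥ 0.5 is adequate" guideline; both
knobs are arguments.

### Missing data

Little's MCAR test uses EM estimates of the mean and covariance under
multivariate normality and sums pattern-wise Mahalanobis distances
(`df = Σ p_j − p`). Imputation is chained equations with predictive mean
matching (5 donors, 10 cycles, 10 imputations by default; binary variables
get logistic draws), so ordinal items can only receive values actually
observed for that item. Networks are fitted per imputed dataset and edge
weights pooled as Rubin point estimates (means); a majority-vote rule for
edge selection is available because regularized estimation and imputation
pooling have no canonical composition — pooling weights keeps edges that a
minority of imputations shrink to zero, majority-vote is stricter.

## The synthetic world

`make_ground_truth()` draws: a temporal matrix `B` with autoregressive
diagonal in (0.15, 0.35) and sparse cross-lagged entries bounded by
`effect_scale` (default 0.4, the upper end of cross-lagged weights
reported in this literature), rescaled if needed to spectral radius < 0.95;
a sparse diagonally-dominant within-person precision `K_w`; a between
covariance `Σ_B` from a sparse random partial-correlation structure; and
equiprobable per-item thresholds (the instruments' marginal distributions
are not publicly reported, so a neutral default; skewed thresholds can be
supplied to emulate floor effects of low-prevalence items such as
suicidality). `simulate_panel()` draws person means, a stationary lag-1
latent process (first wave from the Lyapunov solution
`V = BVB' + K_w⁻¹`), discretizes, and retains the latent array so
estimators can be tested both with and without discretization noise.
Defaults emulate the motivating cohort: ~3000 subjects in two sex strata,
two waves, < 10% MCAR missingness.

What a green recovery test establishes: the estimators find planted
structure of realistic magnitude (|pcor| ≈ 0.3, cross-lagged ≈ 0.4) at
cohort-scale n under MCAR missingness and Likert discretization. What it
does not: robustness to non-normal latent distributions, informative
(MNAR) missingness, measurement non-invariance across groups or waves, or
more than two waves — none of which the generator emulates.

## Numerical choices and degenerate inputs

* Lasso and glasso solvers use exact soft-threshold coordinate descent
  (compiled); zeros are exact, not thresholded output.
* `glasso` convergence: max parameter change < tol (1e-5 default); the
  inner lasso runs at tol/10. The acceptance tests verify the returned
  objective against a dense Nelder-Mead oracle to 1e-6 on 3–4-node
  problems.
* Degenerate scales: constant items are an error naming the item;
  all-equal centralities return zero z-scores with a `degenerate`
  attribute rather than NaN.
* Ties in `top_edges()` break lexicographically by (source, target) so
  reports are reproducible.
* All randomness flows from explicit seeds; pipeline stage seeds are
  derived deterministically from the master seed, and `run_study()` is
  byte-identical under a fixed config and data.
* Reverse-coding defaults to the positively worded procrastination items
  {BPS2, BPS3, BPS7, BPS9} so every node points toward "more
  procrastination"; applied studies label the regular-routine item as
  "irregular bedtime", implying reversal, but never publish the full set —
  hence a documented, overridable default.

## Known limitations

* Two-wave temporal estimates are functionals of the deviation covariance
  (above), not lag coefficients; interpret directionally with care.
* Pearson-on-ordinal attenuates edges; a rank-based correlation hook is
  deliberately not the default to match standard practice.
* The NCT permutes one completed dataset (the first imputation), not the
  full imputation ensemble.
* CS coefficients are reported on the first imputed dataset; imputation
  uncertainty is not propagated into stability profiles.
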