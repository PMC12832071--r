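# panelsym

Longitudinal symptom-network analysis for two-wave ordinal panel data.

`panelsym` is aimed at researchers studying how individual symptoms — here,
bedtime-procrastination behaviours (a 9-item scale scored 1–5) and
adolescent depressive symptoms (an 11-item scale scored 0–3) — predict and
sustain each other over time, rather than treating each questionnaire as a
single latent score. It implements the full analysis pipeline such studies
use, end to end, on any conforming wide-format panel file, and ships a
synthetic-data generator with known network ground truth so that every
estimator is testable by parameter recovery.

## What it computes

* **Gaussian graphical models (GGM).** Items are nodes; edges are partial
  correlations from a sparse precision matrix `K` estimated by the
  graphical lasso, maximizing
  `log det K − tr(SK) − λ Σ_{i≠j} |K_ij|`,
  with `λ` selected on a 100-point path by the extended BIC
  `EBIC = −n(log det K − tr SK) + E log n + 4 E γ log p` (γ = 0.5).
  Node strength `Σ_j |w_ij|` and expected influence `Σ_j w_ij` come
  standardized.
* **Cross-lagged panel networks (CLPN).** Each standardized wave-2 item is
  lasso-regressed on all standardized wave-1 items; `beta[i, j]` is the
  directed effect of item *i* on item *j* 18 months later. Autoregressive
  (self-lag) paths are estimated but set to zero in the displayed network,
  so out-/in-expected influence (OEI/IEI; row/column sums) describe
  between-symptom prediction.
* **Between/within decomposition** in the spirit of panel graphical vector
  autoregression: a between-person partial-correlation network over stable
  person means (with a two-wave within-noise correction), plus temporal and
  contemporaneous within-person networks, all estimated unregularized and
  pruned at a significance level α (default 0.01).
* **Network comparison test (NCT).** Permutation test of global strength
  invariance `S = |Σ|w^A| − Σ|w^B||` and structure invariance
  `M = max |w^A − w^B|` between two groups (e.g. sexes), with Holm-adjusted
  per-edge tests and add-one p-values.
* **Stability.** Nonparametric bootstrap CIs for edges, bootstrap
  edge-difference tests, and case-drop bootstrap CS coefficients (largest
  fraction of subjects that can be dropped while subsample centralities
  keep correlating ≥ 0.7 with the full sample in ≥ 95% of draws; ≥ 0.5 is
  the usual adequacy guideline).
* **Missing data.** Little's MCAR test (EM-based), multiple imputation by
  chained equations with predictive mean matching (logistic draws for
  binary variables), and Rubin's-rules pooling.
* **Synthetic panels.** Latent model `y_it = m_i + η_it` with
  `m_i ~ N(μ, Σ_B)`, stationary lag-1 deviations
  `η_t = B η_{t−1} + ε_t`, `ε ~ N(0, K_w⁻¹)`, discretized by per-item
  thresholds — so `B`, `K_w` and `Σ_B` are the recoverable temporal,
  contemporaneous and between-person truths.

## Worked example

```r
library(panelsym)

truth <- make_ground_truth(p_bps = 4, p_kads = 4, edge_density = 0.25,
                           seed = 101)
study <- simulate_study(truth, n_a = 250, n_b = 250, mcar_rate = 0.05,
                        seed = 201)
cfg <- analysis_config(reverse_items = character(0), n_lambda = 20,
                       n_folds = 5, n_boot_edges = 100, n_boot_casedrop = 10,
                       drop_props = c(0.1, 0.3), n_perm = 100,
                       m_imputations = 2, mice_iterations = 2, seed = 1)
report <- run_study(cfg, data = study$data)
report
```

```
<study_report> groups: female, male 
  missing rate 4.69%; NCT S = 0.000 (p = 1.000), M = 0.000 (p = 1.000)
  female top cross-lagged: KADS4->KADS2 (0.13), KADS3->KADS4 (0.11), BPS3->KADS2 (0.11)
  male top cross-lagged: KADS1->KADS4 (0.17), BPS3->BPS1 (0.13), KADS2->KADS4 (-0.09)
```

Reading: roughly 5% of cells were masked at random; both groups were
simulated from the *same* truth, and the comparison test agrees — at this
group size (n = 250) the EBIC-selected cross-sectional networks are empty
in both groups, so both invariance statistics are 0 with permutation
p-values of 1. The strongest directed edges (standardized lasso coefficients,
self-lags suppressed) are printed per group; `write_report(report, dir)`
exports edge lists, centralities and a JSON summary.

With real data, replace the simulated panel by
`load_panel("panel.csv")` — wide format
`id,sex,BPS1_T1,…,KADS11_T1,BPS1_T3,…,KADS11_T3`, blank or `NA` cells for
missing — and keep the default `reverse_items = NULL` so the positively
worded procrastination items (BPS2/3/7/9) are reflected before estimation.
A command-line front end with `simulate`, `fit`, `compare`, `impute` and
`run` subcommands is in `inst/scripts/panelsym.R`.

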