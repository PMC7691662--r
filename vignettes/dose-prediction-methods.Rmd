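---
title: "Methods: composite visual-health scoring, stability selection, and counterfactual dose recommendation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite visual-health scoring, stability selection, and counterfactual dose recommendation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`lutidose` re-implements, as a tested pipeline, the analysis used to derive
personalized lutein-supplement doses from a 4-arm eye-fatigue randomized
trial: a composite visual health score (VHS), schema-driven preprocessing,
stability-selection feature screening over a boosted-tree depth path, a
cross-validated boosted-tree response model, and a plug-in counterfactual
dose rule. This vignette documents the model, the tunable parameters and
their defaults, the synthetic trial generator that stands in for the
undeposited cohort, the numerical choices, and the known limitations.

## 1. The composite visual health score

Four eye indexes are collected at baseline (V1), day 45 (V2) and day 90
(V3): the total score of eye-fatigue symptoms (TSEFS, points; more symptoms
= worse), visuognosis persistence (VP, seconds), macular pigment optical
density (MPOD, optical-density units), and the Schirmer tear test (ST, mm).
TSEFS, VP and MPOD are approximately normal at baseline and are z-scored
with the sample (n−1) SD convention; ST is right-skewed and is min–max
scaled to [0, 1] on its baseline range. Each transformed component carries
an orientation sign $o_i \in \{\pm1\}$ and

$$\mathrm{VHS} = \tfrac14\sum_i o_i\,t_i(x_i).$$

**Orientation (open design point).** Higher VHS must mean healthier eyes,
but the source analysis never states per-component signs. Defaults:
TSEFS −1 (symptom count), VP +1 (longer persistence of visual recognition
read as better function), MPOD +1 (more protective pigment), ST +1 (more
tear production; low values indicate dry eye). Orientation is a config
argument of `fit_vhs_transforms()` and is recorded in the fitted parameters.

**Frozen baseline transforms.** Parameters (z means/SDs, ST min/max) are fit
on V1 pooled across arms and reused at V2/V3, so score changes are measured
on one scale; follow-up ST values outside the baseline range extrapolate
linearly (the scaled value may leave [0, 1]). The min–max bounds come from
V1 only — using all visits would let follow-up data leak into the baseline
scale. With this convention the three z-components average exactly zero at
baseline, so the mean baseline VHS equals the mean oriented scaled ST over
four — an identity the tests assert to 1e−12.

`ks_normality()` checks the score's normality with a one-sample
Kolmogorov–Smirnov test against a normal with the sample's own mean and SD
(the plain KS statistic; no Lilliefors correction, matching the source
analysis's reported p-value convention).

## 2. The synthetic trial generator

The real cohort is available only on request, so `generate_cohort()` is a
first-class module that emulates its shape with known ground truth.

* **Design.** 303 analyzable subjects, balanced (up to remainder) across
  placebo / 6 / 10 / 14 mg arms. Baseline eye-index moments are calibrated
  to the published trial table: TSEFS 7.6 ± 3.6, VP 99.5 ± 15.7,
  MPOD 0.50 ± 0.17, ST 7.6 ± 6.9 (ST drawn from a gamma with those moments,
  reproducing its non-normality; the others truncated-normal within
  physiologic ranges).
* **Feature panel.** 503 generated baseline features — demographic 6,
  anthropometric 10 (weight/height/body-fat calibrated to the published
  table), blood 57, OCT 34, dietary 391 (200 continuous intake scores, 150
  three-level frequency items, 41 multi-choice FFQ items with 3–8 options) —
  plus the dose (emitted both as arm label and as the numeric mg feature the
  model consumes) and, appended by the pipeline after scoring, the baseline
  VHS itself, giving the 504-feature pool whose ablations leave 447
  (−blood) and 413 (−blood −OCT). Distributions for blood/OCT/dietary
  features are unspecified in the source, so the generator uses plausible
  parametric families (normal with wide declared ranges, lognormal intakes)
  declared alongside the schema.
* **Planted causal structure.** The target VHS change at V2 for subject $j$
  is $\Delta_j = d(\mathrm{arm}_j) + \sum_k \beta_k z_{jk} + r_j +
  \varepsilon_j$ with dose response $d = (0.02, 0.28, 0.38, 0.50)$ VHS units
  for 0/6/10/14 mg (nondecreasing; treated-arm improvements clear the 0.1
  benefit threshold and the 0.22 spread clears the 0.05 indifference
  threshold, so the dominant highest-dose-optimal pattern is recoverable),
  five informative baseline features with coefficients 0.10–0.18 VHS units
  per SD, a latent per-subject responsiveness $r_j \sim N(0, 0.15)$, and
  noise $\varepsilon_j \sim N(0, 0.57)$. The change is written onto the V2
  eye indexes by shifting each oriented transformed component equally, so
  the VHS module sits on the causal path and, in the noiseless limit, the
  per-arm V2 VHS shift equals the configured dose response exactly.
* **Noise calibration.** The noise budget was set once from the variance
  decomposition — signal ≈ var(baseline VHS) 0.16 + dose 0.03 + planted
  effects 0.09 — so the feature-based oracle ceiling
  $\sqrt{R^2} = \mathrm{cor}(\text{best feature-based predictor},
  \mathrm{VHS}_{V2})$ is ≈ 0.67, a realistic regime for composite clinical
  outcomes. The realized ceiling is recorded per cohort in the ground truth
  (latent responsiveness is excluded from the predictable part because no
  baseline feature carries it).
* **Corruption.** `inject_missingness()` masks a configurable fraction
  (default 2%) of baseline cells; `inject_errors()` replaces a fraction
  (default 0.5%) of non-missing cells with schema-violating values (e.g. a
  weight outside [30, 200] kg, an undeclared questionnaire option). Eye
  indexes and dose are exempt from both, keeping the outcome path intact.
  Both attach their positions, so tests can assert the cleaning log matches
  the injected corruption exactly.

What the generator does **not** emulate: enrollment attrition (360 → 303),
dropout dynamics, V3 durability effects, ocular physiology, or correlation
structure among baseline features (they are drawn independently). Passing
tests therefore demonstrate that the pipeline's mechanics are correct and
calibrated under these conditions, not that the published real-data
correlations are reproduced.

## 3. Preprocessing

"Obvious writing mistakes" are operationalised as schema violations: a cell
outside its declared range (continuous), outside the declared levels
(discrete), or containing an undeclared option (multi-choice) is blanked and
logged. Missing continuous cells are imputed with the column mean of
non-missing cases; missing discrete cells take the most frequent level (the
categorical analogue of mean imputation, a choice the source leaves
unstated); missing multi-choice answers become the empty set, which
multi-hot encodes as all zeros. Imputation is fit on the full table before
splitting, mirroring the source's order of operations; this leaks a small
amount of distributional information into the held-out sets and is noted
here deliberately — refit on training only if that matters for your use.

Encoding: continuous features pass through; a discrete feature with k
levels becomes k indicators with row sum exactly 1 (no reference level is
dropped — trees are unaffected by the redundancy and it keeps every level
addressable); a multi-choice feature with m options becomes m indicators.
The split draws an equal number of test subjects per arm (default 7, giving
28 at four arms), then a uniform validation set (default 30) from the
remainder; defaults reproduce the published 245/28/30.

## 4. Stability selection and the threshold rule

For each tree depth λ ∈ {2, …, 10} (the complexity path) and each of 100
random half-subsamples of the training rows, a depth-λ boosted-tree
regressor is fit and a feature counts as *selected* if any of its encoded
columns is used in at least one split — the tree-model analogue of a
nonzero coefficient. Per-depth selection frequencies are aggregated by the
maximum over the path (the classical stability-selection aggregation; mean
is available as config). Subsample membership is drawn by subject id, so
scores are invariant to row order.

Inner fits use deliberately few rounds (20, η = 0.3, `min_child_weight` 5,
histogram method with 16 bins) because only split-usage indicators are
needed, and a minimum-gain regulariser γ = 4 **on a standardised response**
(each fit standardises y, making γ scale-free). Without γ, deep boosted
trees eventually split on every feature and all stability scores saturate
at 1; γ = 4 keeps a noise feature's spurious best split (gain ≈ a few units
at n ≈ 120–150) below the bar while genuine predictors (gain ≈ R²·n per
split) clear it, which is what gives the score its discriminating power.
These values were set by that gain calculus on planted designs and are all
config.

**Threshold choice.** The published rule is "(1) keep reasonably fewer
features; (2) do not lower the 10-fold CV PCC". The package screens a
candidate grid (0.50–0.95 by 0.05) by the CV PCC of a boosted model on the
retained features and keeps the candidates within a tolerance (0.005 PCC)
of the **best attainable over the sweep**, never below the all-features
baseline minus tolerance; among those, fewest features wins, ties toward
the larger threshold. The alternative reading — eligibility relative to the
all-features baseline only — was rejected because a baseline depressed by
hundreds of noise features lets the rule discard genuinely informative
features (any small set beats it), which contradicts both the published
threshold-sweep figure (the chosen threshold sits on the CV-PCC plateau;
larger thresholds visibly lower it) and recoverability on planted designs.
If no candidate clears even the baseline guard, the threshold falls back to
0 with a warning. The dose feature is always retained (forced in),
regardless of score.

An exhaustive mode (`subsample_mode = "exhaustive"`, n ≤ 12) enumerates all
half-subsets and, with the exact depth-1 stump learner, is verified against
an independent brute-force recomputation in the tests.

## 5. Response model and evaluation

Model performance is always Pearson's correlation (PCC) between observed
and predicted VHS; a constant vector is an error, never a silent zero. The
10-fold CV statistic is the per-fold PCC averaged over folds (pooled
predictions available as config). `tune_and_train()` grid-searches xgboost
settings (default grid: depth 2–3, η 0.05/0.1, 300 rounds,
`min_child_weight` 5 — shallow, slow boosting suits n ≈ 245 tabular data)
and refits the winner on the full training set. The quoted training CV is
re-estimated on an independent fold assignment so the grid-search winner's
curse cannot inflate it. Three algorithm families are available on
identical folds for comparison: gradient-boosted trees (xgboost), adaptive
boosting of shallow regression trees (AdaBoost.R2 over `rpart` weak
learners, weighted-median combination), and an elastic net (`glmnet`,
penalty by internal CV). Test and validation sets are never touched during
selection or tuning.

`ablate_feature_groups()` reruns selection (fresh threshold choice) and
training after dropping all encoded columns of named groups — invasive
blood tests, then OCT imaging — and reports the training-CV/test/validation
PCC table side by side with the original model; dropping the dose group is
forbidden.

## 6. Counterfactual dose recommendation

Each held-out subject's encoded feature vector is scored once per candidate
dose (6, 10, 14 mg) with only the dose entry overwritten. The rule, applied
in order with both thresholds in VHS units on the frozen baseline scale:

1. **No benefit** — best predicted V2 VHS exceeds the *measured* baseline
   VHS by ≤ 0.1 (the minimum improvement regarded as meaningful over 45
   days).
2. **Lower dose sufficient (indifference)** — the spread max − min of the
   three predictions is < 0.05, read as the only symmetric single-number
   version of "difference value < 0.05 among 3 doses" (pairwise-all is
   equivalent for three values); the lowest candidate is recommended.
3. **Argmax** — otherwise the dose with the highest prediction (ties to the
   lowest such dose) is recommended: the top candidate gives
   *highest-dose-optimal*, a lower argmax is also reported as
   *lower-dose-sufficient* (so the three categories partition the cohort).

The no-benefit branch is checked first so that a flat, unhelpful prediction
profile is never read as indifference between doses. Placebo-arm subjects
receive counterfactual recommendations like everyone else. The rule is
verified against a brute-force branch enumeration on ~5 × 10⁵ prediction
triples (0.01 lattice on [−0.2, 0.6], four baselines), including
translation invariance — with lattice points sitting exactly on a rule
boundary excluded from the invariance check, since adding a constant in
floating point legitimately flips an exact ≤/< comparison.

## 7. Numerical choices and degenerate inputs

* Zero SD in a z-scored component, a degenerate ST range, fully-missing
  columns, unseen factor levels at encode time, constant CV-fold truth, and
  a missing dose feature at counterfactual time are all hard errors.
* The exact stump learner breaks ties toward the earlier column, then the
  smaller threshold, and only accepts an SSE improvement beyond 1e−12.
* All randomness descends from a single integer seed through a
  deterministic stream-splitting helper; xgboost runs single-threaded, so
  every reported number is bit-reproducible on the same platform.
* Tests and the acceptance script run the full default problem size
  (303 × 504 with two ablations, ≈ 90 s on one CPU); planted-recovery and
  calibration checks use n = 300 designs with p = 100 and a lean ~84-feature
  cohort panel respectively, sizes chosen to keep the whole suite under a
  few minutes while leaving the study conditions (n = 303, noise regime,
  depth path, 100 subsamples) untouched.

## 8. Known limitations

* **Post-selection optimism.** The pipeline quotes the training CV PCC of a
  model whose features were selected using the same training set — the
  source's order of operations. Measured over eight synthetic cohorts at
  the default regime, that quoted CV exceeds honest held-out PCC by ≈ 0.08
  on average (the tuned model on a fixed feature panel shows ≈ 0.01). Use
  the test/validation PCCs for honest performance claims; a nested
  (selection-inside-fold) CV would remove the bias at roughly tenfold
  selection cost and is deliberately not the default.
* Significance claims about VHS differences between arms are out of scope
  (the source does not specify the test behind them).
* Recommendations are plug-in predictions, not causal-inference estimates:
  no propensity adjustment or policy-value machinery, and only the three
  administered doses can ever be recommended.
* The generator's independence across baseline features understates the
  collinearity of real blood/OCT panels; stability scores on real data will
  share credit across correlated features in ways the synthetic tests do
  not exercise.
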