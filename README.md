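# lutidose

Personalized dose recommendation for lutein-based eye-fatigue supplements,
built as a tested, end-to-end R pipeline.

## The problem

Nutritional interventions for eye fatigue (asthenopia) are usually dosed
one-size-fits-all. In a 4-arm randomized controlled trial — placebo and three
daily doses (6, 10, 14 mg lutein) of a botanical combination — subjects differ
in how much a given dose improves their eyes, and in whether a lower dose
would do just as well. `lutidose` implements the analysis pipeline that turns
such a trial into per-subject dose recommendations:

1. **Composite visual health score (VHS).** Four eye indexes — total score of
   eye-fatigue symptoms (TSEFS), visuognosis persistence (VP, s), macular
   pigment optical density (MPOD), and the Schirmer tear test (ST, mm) — are
   combined at each visit as

   $$\mathrm{VHS} = \tfrac14 \sum_{i=1}^{4} o_i\, t_i(x_i),$$

   where $t_i$ is a z-score transform (TSEFS, VP, MPOD; approximately normal
   at baseline) or a min–max scaling to $[0,1]$ (ST; right-skewed), and
   $o_i \in \{\pm 1\}$ orients every component so that higher is better
   (TSEFS counts symptoms, so $o_\mathrm{TSEFS} = -1$). Transforms are fitted
   on baseline data and frozen, so VHS change across visits is measured on a
   common scale.

2. **Preprocessing.** A feature schema (~504 baseline features: demographics,
   anthropometrics, eye indexes, blood biomarkers, OCT retinal thickness,
   dietary/FFQ items, dose) drives cleaning (out-of-range "writing mistakes"
   become missing), mean/mode imputation, one-hot (discrete) and multi-hot
   (multi-choice FFQ) encoding, and an 8:1:1-style split into training
   (n = 245), arm-stratified test (n = 28) and random validation (n = 30).

3. **Stability selection.** Each feature's stability score is the maximum,
   over boosted-tree depths 2–10 (the complexity path), of the fraction of
   100 half-subsample fits in which the feature is used in at least one
   split. The score threshold is chosen to keep the fewest features whose
   10-fold cross-validated Pearson correlation (PCC) stays within tolerance
   of the best attainable; the dose feature is always retained.

4. **Response model.** A gradient-boosted tree regressor (xgboost) predicts
   VHS at day 45 from the selected baseline features; hyperparameters are
   grid-searched by 10-fold CV PCC, with adaptive boosting (AdaBoost.R2) and
   an elastic net available for algorithm comparison on identical folds.

5. **Counterfactual dose recommendation.** Each held-out subject is scored
   three times with the dose entry overwritten by 6, 10, 14 mg. If the best
   predicted VHS beats the measured baseline by ≤ 0.1, the subject cannot
   benefit; if the predictions differ by < 0.05 across doses, the lowest dose
   suffices; otherwise the argmax dose is optimal.

Because the underlying trial data are not publicly deposited, the package
ships a first-class synthetic cohort generator (`generate_cohort()`) that
emulates the trial — 303 subjects, 4 arms, 504 baseline features with
published baseline moments, arm-dependent VHS improvement at day 45, missing
values and out-of-range errors — with full ground truth, so every stage is
testable without any download.

## Worked example

```r
library(lutidose)

fit <- run_dose_pipeline(sim_config(), seed = 1)
print(fit)
#> <dose_pipeline> n = 303 | features: 504 raw / 992 encoded
#>   threshold: 0.95 -> 2 selected
#> # A tibble: 3 x 3
#>   set             n   pcc
#>   <chr>       <int> <dbl>
#> 1 training_cv   245 0.431
#> 2 test           28 0.244
#> 3 validation     30 0.356
#> # A tibble: 3 x 3
#>   category                  n   pct
#>   <chr>                 <int> <dbl>
#> 1 no_benefit                0   0
#> 2 lower_dose_sufficient     7  12.1
#> 3 highest_dose_optimal     51  87.9
```

Reading the output: on this synthetic cohort the stability threshold 0.95
retains two features (baseline VHS and dose — the two the generator makes
genuinely dominant); the model's training 10-fold CV PCC is 0.43 with
held-out PCCs of 0.24 (test, n = 28) and 0.36 (validation, n = 30); of the
58 held-out subjects, 87.9% are predicted to benefit most from the highest
dose and 12.1% would do as well on a lower dose — the same qualitative
pattern the trial analysis reports. Individual numbers move with the seed
because the cohort is simulated.

```r
head(tidy(fit$stability), 3)     # per-feature stability scores
#>   feature         group       score
#> 1 vhs_v1          eye          1
#> 2 age             demographic  0.61
#> 3 diet_intake_156 dietary      0.37
ggplot2::autoplot(fit$stability)        # threshold sweep (features vs CV PCC)
ggplot2::autoplot(fit$recommendations)  # category counts
```

Feature-group ablations (drop invasive blood tests, then costly OCT imaging)
rerun selection and training from scratch and report a side-by-side PCC
table:

```r
ablate_feature_groups(fit)
```

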