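# frailtrans

Frailty-transition classification and gender-stratified prognostic models for
very old, community-dwelling adults.

## The problem

Frailty in old age is commonly operationalised by the five-item phenotype
(shrinking, exhaustion, low physical activity, slowness, weakness): **frail**
with ≥ 3 items, **prefrail** with 1–2, **robust** with 0. Between two study
visits a participant's state can **improve** (e.g. frail → prefrail),
**worsen** (e.g. robust → prefrail, and death from any state counts as
worsening), or stay unchanged; survivors whose follow-up state cannot be
scored are **unknown**. Epidemiologists studying such cohorts want
gender-stratified prognostic models: which baseline characteristics predict
improvement or worsening over roughly two years?

`frailtrans` implements that analysis end to end, for anyone with a
participant-level table (or no data at all — a calibrated synthetic-cohort
generator is included):

1. **Phenotype scoring** with a conservative missing-item rule: a state is
   assigned only when it is invariant to every completion of the missing
   items, otherwise the profile is *indeterminate*.
2. **Transition classification** under the severity order
   robust < prefrail < frail, with death overriding any recorded follow-up.
3. **Predictor derivation** at the standard cutpoints (eGFR < 60 ml/min/1.73 m²,
   ACR ≥ 30 mg/g, ≥ 5 medications, HbA1c ≥ 6.5 % or antidiabetic drug, BMI and
   hospitalisation bands).
4. **Multiple imputation by chained equations** (M = 10 by default), with the
   follow-up state in the imputation model and death never imputed.
5. **Bootstrap-stability variable selection**: 200 bootstrap resamples per
   imputed dataset, automatic backward elimination by AIC
   (AIC = 2k − 2 log L) on each, and selection of candidates retained in
   ≥ 50 % of the M × 200 samples.
6. **Rubin's-rules pooling** of the selected logistic model
   (T = W + (1 + 1/M)·B, Barnard–Rubin degrees of freedom), reported as odds
   ratios with 95 % CIs.
7. **Internal validation**: Harrell's optimism-corrected c-index with a
   bootstrap-SE confidence interval, and bias-corrected calibration intercept
   and slope with decile calibration-curve data.

## Worked example

```r
library(frailtrans)

cfg      <- default_bis_config()          # published per-gender marginals
cohort   <- generate_cohort(cfg, seed = 42)
classified <- classify_cohort(cohort$records)
transition_summary(classified)
```

```
Frailty transitions: 470 transitioned (46% of determined, 41% of all); 137 deaths (46% of worsened)
      improvement no_change worsening unknown
woman          93       318       149      77
man            77       243       151      50
total         170       561       300     127
```

One of the four gender × outcome models (reduced settings for a quick run):

```r
women <- classified[classified$gender == "woman", ]
stack <- impute_cohort(women, m = 5, iterations = 5, seed = 43)
sel   <- stability_select(stack, selection_config("worsening",
           bootstraps_per_imputation = 50, seed = 44))
fit_on_stack(stack, sel$selected, "worsening")
validate_model(stack, sel$selected, "worsening", bootstraps = 100,
               auc_reps = 1000, calibration_bootstraps = 100, seed = 45)
```

```
Pooled logistic model (worsening): n = 637, events = 163, m = 5
  (Intercept)                  OR   0.13 ( 0.06-  0.24)
  bmi_cat25-29.9               OR   0.92 ( 0.61-  1.40)
  bmi_cat>=30                  OR   0.62 ( 0.36-  1.07)
  cancerTRUE                   OR   1.51 ( 0.92-  2.49)
  egfr_lt60TRUE                OR   1.68 ( 1.01-  2.79)
  frailty_baselineprefrail     OR   1.65 ( 1.07-  2.54)
  frailty_baselinerobust       OR   3.48 ( 1.87-  6.50)
  hospitalization_cat1-2       OR   1.53 ( 0.95-  2.46)
  hospitalization_cat>=3       OR   1.15 ( 0.67-  1.96)
Internal validation (worsening): c-index 0.63 (0.58-0.67)
Bias-corrected calibration: intercept -0.01 to 0.01, slope 0.80 to 0.87 (m = 5)
```

Reading the output: under the default (empirical-matrix) transition
mechanism only baseline frailty status truly drives the outcome, and it is
what the model leans on — a baseline-robust woman has ~3.5-fold odds of
worsening relative to a frail one (who can only worsen by dying, so her
worsening *rate* is driven by mortality). The other retained terms are
finite-sample noise hovering near the 50 % selection threshold; the
events-per-parameter warning flags exactly this. The corrected c-index
(0.63) is honest discrimination after removing bootstrap optimism, and a
calibration slope below 1 (0.80–0.87) measures the usual overfitting
shrinkage. To study covariate-driven transitions, switch the generator to
its logistic mechanism (`cohort_config(..., mechanism = "logistic")`) with
coefficients of your choosing.

`run_full()` orchestrates all four models (improvement and worsening for
each gender; no-change is structurally not modellable) and returns the
descriptive tables, transition matrices, selection frequencies, pooled
models, validation reports and a reproducibility manifest.

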