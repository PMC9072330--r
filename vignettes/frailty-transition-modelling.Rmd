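---
title: "Modelling frailty transitions: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling frailty transitions: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtrans)
```

This vignette is the package's account of its statistical machinery: the
models, their assumptions, the tunable parameters, and the choices made
where the design was genuinely open.

## The phenotype and its missing-item rule

The five-item frailty phenotype maps item counts to categories: 0 → robust,
1–2 → prefrail, ≥ 3 → frail. With partially observed items the category may
or may not be identifiable, and `classify_frailty()` assigns a state only
when it is *invariant to every completion* of the missing items:

* frail whenever the observed positives already reach 3;
* robust only with five observed negatives;
* prefrail only when positives ∈ {1, 2} and positives + missing ≤ 2, so no
  completion can reach the frail threshold and none can reach zero;
* indeterminate otherwise.

This rule never guesses, reproducing the common practice of excluding
participants whose baseline score cannot be computed, and it is tested
against brute-force enumeration of all completions of every possible
(positive, negative, missing) composition. Item *operationalisation* (grip
strength and gait-speed cutoffs, activity questionnaires) is site-specific
and deliberately outside the package: items arrive pre-scored as
present/absent/missing.

Transitions use the severity order robust < prefrail < frail. Death within
the follow-up window is worsening from any state and overrides recorded
follow-up items, because dates of death are typically ascertained from
claims or registry data and are reliable even when the follow-up visit did
not happen. Deaths after the individual follow-up interval are not counted
(the window is the participant's own baseline → follow-up interval).
Survivors with an indeterminate follow-up state are `unknown` and drop out
of the modelling denominators, not of the descriptives.

## The synthetic cohort generator

Real participant-level data of this kind are not redistributable, so the
generator exists as a first-class, tested module. Its default configuration
(`default_bis_config()`) encodes the published per-gender marginals of a
large urban cohort of adults aged 70+: 637 women and 521 men; baseline
states 115/282/240 (women) and 110/250/161 (men); covariate prevalences
taken among known values; per-field missingness equal to the published
"unknown" fractions; age normal (84.1 ± 5.6 women, 84.8 ± 5.7 men)
truncated at the eligibility age of 70.

Two transition mechanisms are available:

* **Empirical matrix** (default): each participant's destination (robust /
  prefrail / frail / death) is drawn from a per-gender 3 × 4 row of their
  baseline state. The per-cell figures are not published numerically; the
  default matrices are reconstructed from the per-gender composition of the
  improvement / no-change / worsening groups by baseline state, the
  per-state death fractions (≈ 2 % robust, 6 % prefrail; frail deaths 18 %
  of women, 33 % of men), and the observation that adjacent-state moves
  dominate. They are therefore approximate in the within-worsening and
  within-improvement splits, and flagged as such. Deaths are exact by
  construction; unknowns are assumed to follow the observed survivor
  destination distribution within their state (an MAR assumption).
* **Logistic**: worsening is drawn first with probability
  `plogis(a + x'b)` from configured coefficients, then improvement among
  surviving non-robust non-worseners. The worsening log-odds are exactly
  linear in the configured coefficients, which is what the
  parameter-recovery tests exercise. Destination detail inside worsening
  (death versus frail for prefrail worseners, the robust worsener split)
  follows fixed conditional splits with documented defaults.

Loss to follow-up is a single per-gender Bernoulli rate applied to
survivors, chosen so the expected unknown count matches the published one
(70 women, 59 men). Covariate dependence is a Gaussian copula over latent
normal scores, default independence, because only marginals are published.
Baseline items for a drawn state use a uniform positive count in the
state's defining range with uniform item identities — states, not items,
drive everything downstream.

**What the generator does not emulate** (and hence what passing tests do
not show about real data): covariate–transition dependence in the matrix
mode (only baseline state carries signal there); the higher loss to
follow-up of frail participants; item-level correlation structure;
MNAR missingness; and anything longitudinal beyond one interval.

## Imputation

`impute_chained()` is a chained-equations engine with proper parameter
draws: Bayesian linear regression for continuous variables (predictive-mean
matching behind `pmm = TRUE` for users who prefer it; the Bayesian draw is
the default because its behaviour is analytically checkable), logistic
draws for binary variables, and multinomial-logistic draws (via `nnet`) for
unordered categories. Ten chained sweeps per dataset is the default — the
common chained-equations convention — and M = 10 imputations mirror
standard practice for this amount of missingness; both are configurable.
Degenerate conditional fits (separation is routine in small bootstrap
strata) fall back to a small L2 penalty (`ridge = 1e-2` on standardised
logistic designs, weight decay 0.05 for multinomial fits) rather than
failing.

Cohort-specific wrapper `impute_cohort()` resolves an interpretation point
explicitly: the *follow-up frailty state* (three levels, survivors only) is
imputed — death is fully observed and never imputed, nor ever drawn for a
survivor — and the composite transition outcome is recomputed afterwards in
every completed dataset, keeping the death override exact. Imputation is
run per gender stratum, matching the fully gender-stratified analysis and
avoiding cross-gender borrowing in the conditional models.

Pooling follows Rubin's rules with Barnard–Rubin small-sample degrees of
freedom and t-based interval quantiles; at these sample sizes the
difference from normal quantiles is negligible, but the t form is the
reporting convention for multiply imputed model development. Published-style
event counts after imputation are the rounded mean of per-imputation event
counts.

## Variable selection

`stability_select()` draws `bootstraps_per_imputation` (default 200)
resamples from each imputed dataset — within the gender stratum, resample
size equal to the analysis n — and applies `backward_select_aic()` to each:
greedy elimination of the term whose removal lowers AIC most, stopping when
no removal lowers it. Candidates retained in at least
`frequency_threshold` (default 50 %) of the M × B samples form the selected
set.

Determinism required two policies the greedy rule itself does not fix:

* **Term blocks**: multi-level factors (education, BMI band,
  hospitalisation band, baseline frailty status) enter and leave as whole
  terms. Whether the original backward selections treated dummies
  separately is unverifiable; blocks keep the factor's levels interpretable
  as one predictor.
* **Tie-breaks**: AIC ties (within 1e-8) drop the term with the smallest
  maximum |Wald z| in the current fit, residual ties resolve by
  alphabetical candidate order. With a data-driven primary key, permuting
  the candidate argument provably cannot change the result, and a test
  asserts exactly that.

Improvement models are fit on baseline prefrail + frail participants only —
a robust participant cannot improve, and the published model denominators
(gender n minus baseline-robust n) force this reading. Baseline frailty
status is an ordinary candidate with reference level frail. An
events-per-parameter guard warns (never fails) below 10 events per
parameter. Resamples with zero or all events are redrawn up to 10 times,
then skipped with the tally denominator adjusted.

## Internal validation

`c_index()` is the tie-aware pairwise concordance probability, computed by
midranks (identical to pair enumeration, and cross-checked against an
independent implementation in the tests). The optimism correction is
Harrell's loop: refit the model on each bootstrap resample, subtract its
original-data performance from its resample performance, and remove the
average inflation from the apparent value. Two open points were resolved as
follows, both logged here deliberately:

* The loop refits the **fixed selected term set**; selection is not re-run
  inside validation bootstraps. The analysis sequence places selection
  before validation, and re-selection — which would make the correction
  more conservative — is not described; users wanting the fully honest
  variant can run `stability_select()` inside their own
  `harrell_optimism()` fit function.
* The single reported c-index pools the per-imputation corrected values by
  simple mean.

The AUC confidence interval uses the bootstrap standard error of the
c-index (default 2000 resamples of the score–outcome pairs, computed on the
first completed dataset's apparent scores) around the corrected pooled
value, truncated to [0, 1]. Calibration uses the logistic recalibration
framework — slope from regressing the outcome on the linear predictor,
intercept from the offset model — with the same Harrell correction applied
per imputation, and a decile-binned calibration curve (quantile bins, no
smoother, so no bandwidth choices) per imputation.

## Numerical choices and degenerate inputs

* Logistic fits flag separation (boundary fitted probabilities, huge or
  non-finite coefficients, non-convergence) and refit with ridge-stabilised
  IRLS; the intercept is never penalised.
* Exact linear dependence in `vif()` is reported as `Inf` with a flag
  (threshold 5, the usual rule of thumb; no threshold is standard enough to
  fail on).
* AIC comparisons use an absolute tolerance of 1e-8; bootstrap resampling
  uses `sample.int` under per-stage seeds derived from the global seed, so
  `run_full()` is bitwise reproducible.
* Zero between-imputation variance short-circuits the Barnard–Rubin
  formula to the complete-data df (fraction of missing information 0).

## Problem sizes used by the test-suite

The suite exercises every stage at sizes chosen to make the statistical
assertions sharp while keeping a full run in a few minutes on one core:
enumeration oracles at n ≤ 2^5 profiles, generator calibration at the
published stratum sizes (637/521) over 50–200 replicate seeds, imputation
coverage at n = 400 over 60 replicates, selection bookkeeping at the full
default 10 × 200 = 2000 samples (n = 600, five candidates), parameter
recovery at n = 4000–5000 with reduced settings (M = 3, B = 50), and the
overfitting-direction checks at n = 200 with 10 noise predictors over 50
replicates. These are the package's own choices of demonstration scale;
all thresholds were fixed from the sampling arithmetic (2–3 standard
errors) rather than tuned.

## Known limitations

* The default transition matrices are reconstructions; their within-group
  destination splits are approximate by necessity.
* The matrix mechanism makes transitions independent of covariates given
  gender and baseline state, so models fit on default synthetic cohorts
  select mostly baseline status plus noise — by design, and the worked
  example says so.
* No competing-risk time-to-event treatment of death (the outcome is a
  two-year status change, as in the source design), no MNAR sensitivity
  analysis, no external validation, no Firth correction, and no
  interaction or spline terms.
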