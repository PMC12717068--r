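# screenaudit

Auditing the effect of race and ethnicity on an advanced breast cancer
risk prediction model.

Clinical risk models sometimes include race and ethnicity because disease
incidence differs across groups; "race-naive" modeling is proposed as a
remedy for algorithmic bias. `screenaudit` implements a complete,
reproducible audit of that trade-off for screening-based advanced breast
cancer risk prediction: it fits per-screening-round risk models with and
without race and ethnicity, compounds them into cumulative 6-year risks
under competing events, and quantifies how removing race shifts
calibration, discrimination, and percentile-based risk-category assignment
by race group. Because real screening-registry data are confidential, the
package ships a synthetic-cohort generator that emulates the covariate
structure, rare outcome rates, race-specific effects, and item-level
missingness such an audit assumes — so every result is reproducible from
code alone.

It is intended for biostatisticians and epidemiologists studying prediction
model fairness, and as a reference implementation of the audit pipeline.

## The model

One row per screening mammogram. Within each stratum *s* = menopausal
status × screening interval, two logistic models are fit per round:

- advanced cancer within the follow-up window (12 months after an annual
  screen, 24 after a biennial one):
  `logit q(x) = α_s + β₁ age + β₂ age² + γ'x`
- a competing event (death or early-stage cancer), conditional on no
  advanced cancer, with the same covariate structure.

Covariates *x* are race and ethnicity (five groups; omitted in the
race-excluded variant), first-degree family history, benign biopsy history,
BMI category, and BI-RADS density. Missing covariates are multiply imputed
by chained equations (*m* = 15) and per-exam predictions are pooled by
averaging over imputations.

Cumulative 6-year risk over *K* rounds (6 annual or 3 biennial screens)
follows the discrete-time cause-specific form

```
risk = Σ_k q_k · Π_{j<k} (1 − q_j)(1 − c_j)
```

with q advanced and c competing per-round probabilities along the ageing
covariate profile. Evaluation uses the expected/observed ratio
`E/O = Σ predictions / Σ events` per race group (1 = perfect mean
calibration), 5-fold cross-validated Mann–Whitney AUC, and five weighted
percentile risk categories (very low ≤5th, low ≤25th, average ≤75th,
intermediate ≤95th, high >95th), each model variant using thresholds from
its own risk distribution.

## Worked example

```r
library(screenaudit)

cfg    <- generator_config(n_women = 50000, seed = 11)
cohort <- simulate_cohort(cfg, mask = FALSE)$complete

fit_inc <- fit_round_models(cohort, model_spec(include_race = TRUE))
fit_exc <- fit_round_models(cohort, model_spec(include_race = FALSE))

eo <- rbind(
  expected_observed(predict_round_risk(fit_inc, cohort, "advanced"),
                    cohort$outcome, cohort$race_ethnicity, "include_race"),
  expected_observed(predict_round_risk(fit_exc, cohort, "advanced"),
                    cohort$outcome, cohort$race_ethnicity, "exclude_race"))
tidyr::pivot_wider(eo[, c("group", "variant", "eo_ratio")],
                   names_from = "variant", values_from = "eo_ratio")
#>   group          include_race exclude_race
#> 1 Asian                  1.00        1.59
#> 2 Black                  1.00        0.600
#> 3 Hispanic               1.00        1.11
#> 4 Other/Multiple         1.00        0.756
#> 5 White                  1.00        1.05
```

The race-aware model is exactly calibrated within every race group — a
consequence of the logistic maximum-likelihood score equations, since the
race indicators are in the model. Removing race leaves nothing to absorb
the group differences: under a generating model with a twofold odds
elevation for Black women and a 0.7-fold reduction for Asian women, the
race-excluded model underestimates risk for Black women (E/O = 0.60) and
overestimates it for Asian women (E/O = 1.59).

The same bias propagates into risk categories. Among women who develop
advanced cancer:

```r
adv  <- cohort$outcome == "advanced_cancer"
cr_i <- cumulative_risk(cohort, fit_inc)
cr_e <- cumulative_risk(cohort, fit_exc)
thr_i <- compute_thresholds(cr_i$risk_pct, variant = "include_race")
thr_e <- compute_thresholds(cr_e$risk_pct, variant = "exclude_race")
compare_models(
  intermediate_high_share(cr_i$risk_pct, thr_i, cohort$race_ethnicity, adv),
  intermediate_high_share(cr_e$risk_pct, thr_e, cohort$race_ethnicity, adv))
#>   race           status   include_race exclude_race  delta
#> 1 Asian          advanced         13.6         38.6  25.00
#> 2 Black          advanced         82.9         49.6 -33.33
#> ...
```

Excluding race, the share of Black women with advanced cancer who would be
flagged intermediate/high risk drops from 82.9% to 49.6% — they lose access
to intensified screening precisely because the model no longer sees their
elevated risk — while the share among Asian women rises.

`run_pipeline(pipeline_config(...), out_dir)` chains the whole audit
(generate → mask → impute → fit both variants → evaluate → cumulate →
stratify → compare) and writes the cohort, all result tables, fitted-model
JSON, and a run manifest; `plot_calibration()`, `plot_risk_distribution()`,
`plot_category_prevalence()` and `autoplot()` visualize the results, and
`tidy()` / `glance()` expose fitted models broom-style.

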