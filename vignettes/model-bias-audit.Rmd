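---
title: "Auditing race-aware versus race-free advanced breast cancer risk models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing race-aware versus race-free advanced breast cancer risk models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Advanced breast cancer (invasive disease of prognostic pathologic stage II
or higher found within the screening follow-up window) is a surrogate for
breast cancer mortality, and models of its 6-year risk are used to guide
decisions about screening interval and supplemental imaging. Such models
commonly include race and ethnicity because advanced-cancer rates differ
substantially across groups — roughly twofold higher per screen for Black
than for White women, and lower for Asian women. "Race-naive" modeling has
been proposed to address algorithmic bias; this package quantifies what
that removal actually does to model performance, group by group.

The audit compares two variants of the same model that differ only in the
presence of race and ethnicity indicators, along three axes:

1. **Calibration**: the expected/observed (E/O) ratio of advanced cancers
   after one screening round within each race group.
2. **Discrimination**: cross-validated AUC, overall and by group.
3. **Risk stratification**: weighted percentile categories of cumulative
   6-year risk, and the reclassification of women (with and without
   advanced cancer) between the two variants.

## The model and its assumptions

The screening mammogram is the unit of analysis. Within each of the four
strata formed by menopausal status (pre/post) and screening interval
(annual/biennial), the advanced-cancer probability for an exam with
covariates $x$ is logistic:

$$\operatorname{logit} q(x) = \alpha_s + \beta_1\,\mathrm{age} +
\beta_2\,\mathrm{age}^2 + \gamma^\top x,$$

with $x$ comprising race and ethnicity (five groups, White reference;
omitted in the race-excluded variant), first-degree family history, benign
biopsy history (five levels), BMI category (five levels), and BI-RADS
density (four levels). A second logistic model of the same form describes
competing events (death or early-stage cancer) *conditional on no advanced
cancer in the same window* — the tree factorization of the three-state
per-exam outcome. A multinomial formulation would be an alternative; the
tree form was chosen because it lets each cause be fit by ordinary logistic
maximum likelihood and matches how the per-round probabilities enter the
discrete-time compounding.

Cumulative 6-year risk for a covariate profile compounds the per-round
predictions over $K$ rounds ($K = 6$ annual, $K = 3$ biennial):

$$\mathrm{risk} = \sum_{k=1}^{K} q_k \prod_{j<k} (1 - q_j)(1 - c_j),$$

where $q_k$ and $c_k$ are the advanced and competing probabilities at
round $k$, predicted from the profile with age advanced by the nominal
interval length (+1 year per annual round, +2 per biennial). Within a
round, advanced cancer is evaluated before the competing event, so
per-round event-free survival is $(1-q)(1-c)$. Two deliberate
simplifications are documented rather than resolved: ages advance by
nominal interval lengths (not observed mean inter-screen times), and the
menopause stratum is frozen at its baseline value across rounds (no
pre-to-post transition during the horizon).

### Why the race-aware model is exactly calibrated per group

The logistic score equations at the MLE satisfy $X^\top(y - \hat p) = 0$.
Every 0/1 column of the design — including each race indicator — therefore
has its predicted event total equal to its observed total, so the
in-sample E/O ratio is exactly 1 within every race group whenever race is
in the model. This identity (verified to 10⁻⁶ in the tests) is the
mechanism behind the race-aware variant's column of 1.00s, and its loss is
precisely what the audit measures: on data generated with a twofold odds
elevation for one group, the race-excluded variant's E/O for that group
falls below 1 (underestimation) by roughly the inverse of the suppressed
odds ratio, with the complementary overestimation in reduced-risk groups.

## The synthetic-cohort generator

Registry data of this kind are confidential, so the generator is a
first-class, tested module that defines the study conditions:

- **Structure.** One row per exam; five race/ethnicity groups with
  probabilities 0.099/0.094/0.048/0.018/0.741 (Asian, Black, Hispanic,
  Other/Multiple, White), a 77/23 annual/biennial split, ages uniform on
  40–74, and per-race covariate distributions (Asian women denser and
  leaner, Black women less dense and heavier — the directions seen in
  screening cohorts). One observed round per woman by default.
- **Outcomes.** Drawn from the same two-logistic tree the analysis fits,
  with race effects $+\log 2$ (Black), $\log 0.7$ (Asian), $+\log 1.2$
  (Other/Multiple) versus White, graded density/biopsy/BMI/family-history
  effects, and a mild quadratic age trend.
- **Rates.** Real per-exam advanced-cancer rates (0.03–0.16%) would leave
  desk-scale cohorts nearly event-free, so the default baseline inflates
  them about tenfold (≈0.4–1% per round at the reference profile);
  `realistic_rates = TRUE` restores real-world magnitudes without changing
  structure. Competing events run at ≈1%/2% per annual/biennial round and
  are not inflated.
- **Missingness.** Independent per-variable masking with defaults shaped
  like observed screening data (BMI ≈ 35%, menopause ≈ 18%, race ≈ 4.5%,
  family history ≈ 3.8%, density ≈ 2%), MCAR by default with optional
  logistic dependence on age and interval (the simplest
  missing-at-random mechanism chained-equation imputation can correct).

What the generator does **not** emulate: within-woman covariate dependence
beyond the configured race conditionals (e.g. a density–BMI correlation),
multiple exams per woman with evolving covariates, registry exclusion
cascades, and tumor biology beyond the three-state outcome. Passing tests
therefore demonstrate correctness of the audit machinery under a known
generating law — not that any particular real cohort satisfies that law.

## Imputation

Chained equations with categorical conditionals: binary covariates
(menopause, family history) by logistic regression, multi-level covariates
(race, biopsy, density, BMI) by multinomial logistic regression, each
given all other covariates, age, interval and the observed outcome.
Defaults: $m = 15$ completions, 10 sweeps, visit order by ascending
missingness, initial fill from observed marginals, independent
per-completion seeds derived from the master seed. Unknown menopausal
status resolves to pre or post only. Predictions are pooled across
completions by the arithmetic mean on the probability scale (the variant
of pooling appropriate when the target is a risk score rather than a
coefficient); no Rubin's-rules variance pooling is attempted for
predictions, and between-imputation spread is reported descriptively.
Imputation runs once on the full dataset before cross-validation; this
mirrors the common single-imputation-first workflow but leaks information
across folds, so the caveat is documented and per-fold refitting of the
models (though not of the imputations) is what the CV implementation does.
With zero missingness the imputation layer is the exact identity, and the
full imputed pipeline reproduces the complete-case pipeline bit for bit —
a tested invariant.

## Numerical choices

- Age enters fitting on an internally standardized scale
  ((age − 57)/10 and its square) for conditioning of the raw quadratic;
  coefficients and covariances are mapped back to the raw age/age² basis
  before reporting, so users only ever see raw-scale terms.
- Maximum-likelihood fits are polished by Newton steps until the score
  norm is below 10⁻⁸; separation or non-convergence triggers a
  Firth-penalized (Jeffreys-prior) fallback, recorded per fit and never
  silent. Covariate levels absent from a stratum are dropped from that
  stratum's fit and reported as zero coefficients with missing standard
  errors.
- Weighted percentiles use the left-continuous cumulative-weight rule (the
  smallest observed value whose cumulative normalized weight reaches
  $p$), applied uniformly to thresholds, medians and IQRs; risks exactly
  at a threshold take the lower category.
- Standardization weights are reference-cell proportion over cohort-cell
  proportion on age-group × race × family-history cells; the cohort's own
  distribution is the default reference (all weights 1), and any supplied
  reference is validated for full support and renormalized.
- Bootstrap intervals resample women, not exams, preserving within-woman
  clustering; E/O replicates with no observed events are dropped and
  counted, with a warning flag above 10% dropped. Cross-validation folds
  partition women, stratified by case status via round-robin dealing over
  a seed-shuffled order, so events appear in every fold; the AUC is
  computed once over all out-of-fold predictions (stabler than averaging
  fold AUCs when events are rare).

## Problem sizes and verification

The test suite checks every operation against an independent oracle:
closed forms, brute-force enumeration of the full 3^K outcome tree,
Monte-Carlo simulation (10⁶ replicates for the compounding law), an
independent AUC implementation, leave-one-woman-out refitting, and
parameter recovery from the generator's known truth. The larger
property checks run on cohorts of 40,000–200,000 exams with fixed seeds —
sizes at which binomial Monte-Carlo error is small compared to the
assertion tolerances while the whole suite stays fast; the acceptance
script uses 200,000 exams. One caveat surfaced by the recovery check is
worth knowing: with ~44 fitted coefficients, a correctly specified MLE is
expected to place a few estimates slightly beyond two standard errors of
truth by chance alone, so joint "all within 2 SE" assertions are
statistically strict at this scale even when the fits are exactly right
(the score-equation and AUC oracles confirm they are).

## Known limitations

- The audit is in-sample for calibration (as the score identity requires)
  and cross-validated only for discrimination.
- Cumulative risks extrapolate the age polynomial up to five years beyond
  the oldest fitting age for women entering at 74.
- The generator's covariate independence means imputation is easier here
  than on real data; MICE performance on strongly dependent covariates is
  not demonstrated by these tests.
- Clinically optimal risk thresholds, screening harms, and real-registry
  ingestion are out of scope.
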