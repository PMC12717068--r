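ref_record <- function(age = 60, interval = "annual", menopause = "post") {
  tibble::tibble(
    woman_id = "W1", round_index = 1L, interval = interval, age = age,
    race_ethnicity = "White", menopause = menopause, family_history = "no",
    biopsy_history = "none", density = "fatty", bmi = "normal",
    outcome = "none"
  )
}

# A hand-built fit with known coefficients, for closed-form prediction checks.
manual_fit <- function(spec, coef_fun) {
  terms <- colnames(encode_covariates(ref_record(), spec))
  one <- setNames(lapply(stratum_labels(), function(s) {
    beta <- coef_fun(terms)
    f <- list(coefficients = beta, se = beta * 0, penalized = FALSE,
              converged = TRUE, n = 1, events = 1)
    list(advanced = f, competing = f)
  }), stratum_labels())
  structure(list(variant = spec$variant, spec = spec, fits = list(one),
                 m = 1L),
            class = "round_model_fit")
}

test_that("covariate encoding produces the documented design row", {
  spec <- model_spec(TRUE)
  X <- encode_covariates(ref_record(age = 60), spec)
  expect_equal(unname(X[1, "age"]), 60)
  expect_equal(unname(X[1, "age_sq"]), 3600)
  expect_equal(unname(X[1, "(Intercept)"]), 1)
  # All-reference record: every indicator is zero.
  ind <- setdiff(colnames(X), c("(Intercept)", "age", "age_sq"))
  expect_true(all(X[1, ind] == 0))

  # Include- vs exclude-race rows differ exactly by the race block.
  X2 <- encode_covariates(ref_record(), model_spec(FALSE))
  expect_setdiff <- setdiff(colnames(X), colnames(X2))
  expect_identical(sort(expect_setdiff),
                   sort(paste0("race_ethnicity=",
                               setdiff(race_levels(), "White"))))
  common <- colnames(X2)
  expect_identical(X[, common], X2[, common])

  bad <- ref_record(); bad$density <- "mosaic"
  expect_error(encode_covariates(bad, spec),
               class = "screenaudit_encoding_error")
})

test_that("round-risk predictions equal the closed-form inverse logit", {
  spec <- model_spec(TRUE)
  null_fit <- manual_fit(spec, function(terms) {
    setNames(rep(0, length(terms)), terms)
  })
  expect_equal(predict_round_risk(null_fit, ref_record(), "advanced"), 0.5)

  int_fit <- manual_fit(spec, function(terms) {
    b <- setNames(rep(0, length(terms)), terms)
    b["(Intercept)"] <- qlogis(0.01)
    b
  })
  expect_equal(predict_round_risk(int_fit, ref_record(), "advanced"), 0.01,
               tolerance = 1e-12)

  # Direct dot-product oracle on arbitrary records and coefficients.
  set.seed(42)
  sim <- test_cohort(n_women = 50, seed = 41)
  rec <- sim$complete
  beta <- NULL
  rand_fit <- manual_fit(spec, function(terms) {
    if (is.null(beta)) {
      beta <<- setNames(c(-6, 0.02, -1e-4, rnorm(length(terms) - 3, 0, 0.4)),
                        terms)
    }
    beta
  })
  pred <- predict_round_risk(rand_fit, rec, "advanced")
  X <- encode_covariates(rec, spec)
  expect_equal(pred, plogis(drop(X %*% beta)), tolerance = 1e-12)
})

test_that("maximum-likelihood fits satisfy the score-equation identity", {
  sim <- test_cohort(n_women = 8000, seed = 43)
  rec <- sim$complete
  spec <- model_spec(TRUE)
  fit <- fit_round_models(rec, spec)
  td <- tidy(fit)
  expect_false(any(td$penalized[td$event == "advanced"]))

  strata <- paste(rec$menopause, rec$interval, sep = ".")
  pred <- predict_round_risk(fit, rec, "advanced")
  for (s in stratum_labels()) {
    for (r in race_levels()) {
      idx <- strata == s & rec$race_ethnicity == r
      if (!any(idx)) next
      expect_equal(sum(pred[idx]),
                   sum(rec$outcome[idx] == "advanced_cancer"),
                   tolerance = 1e-6)
    }
    # Whole-stratum identity via the intercept column.
    idx <- strata == s
    expect_equal(sum(pred[idx]),
                 sum(rec$outcome[idx] == "advanced_cancer"),
                 tolerance = 1e-6)
  }
})

test_that("fits are invariant to row permutation", {
  sim <- test_cohort(n_women = 2000, seed = 47)
  rec <- sim$complete
  spec <- model_spec(FALSE)
  f1 <- fit_round_models(rec, spec)
  set.seed(1)
  f2 <- fit_round_models(rec[sample(nrow(rec)), ], spec)
  c1 <- f1$fits[[1]][["post.annual"]]$advanced$coefficients
  c2 <- f2$fits[[1]][["post.annual"]]$advanced$coefficients
  expect_equal(c1, c2, tolerance = 1e-8)
})

test_that("strata without events raise fitting errors rather than fitting silently", {
  sim <- test_cohort(n_women = 1000, seed = 49)
  rec <- sim$complete
  rec$outcome[rec$menopause == "pre" & rec$interval == "annual"] <- "none"
  expect_error(fit_round_models(rec, model_spec(TRUE)),
               class = "screenaudit_fitting_error")
})

test_that("tidy and glance expose coefficients and fit summaries", {
  sim <- test_cohort(n_women = 2000, seed = 51)
  fit <- fit_round_models(sim$complete, model_spec(TRUE))
  td <- tidy(fit)
  expect_true(all(c("stratum", "event", "term", "estimate",
                    "std.error") %in% names(td)))
  expect_setequal(unique(td$stratum), stratum_labels())
  g <- glance(fit)
  expect_equal(g$n, nrow(sim$complete))
  expect_equal(g$events_advanced,
               sum(sim$complete$outcome == "advanced_cancer"))
})
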