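test_that("expected/observed ratios follow their defining arithmetic", {
  eo <- expected_observed(c(0.2, 0.4), c("none", "advanced_cancer"))
  expect_equal(eo$expected, 0.6)
  expect_equal(eo$observed, 1)
  expect_equal(eo$eo_ratio, 0.6)

  # A group without events is flagged, not infinite.
  eo2 <- expected_observed(c(0.2, 0.3), c("none", "none"),
                           c("a", "a"))
  expect_false(eo2$estimable)
  expect_true(is.na(eo2$eo_ratio))

  # Pooled E/O is the events-weighted combination of group E/Os.
  set.seed(11)
  preds <- runif(300, 0, 0.3)
  outc <- ifelse(runif(300) < 0.15, "advanced_cancer", "none")
  grp <- sample(letters[1:3], 300, replace = TRUE)
  by_grp <- expected_observed(preds, outc, grp)
  overall <- expected_observed(preds, outc)
  expect_equal(sum(by_grp$expected) / sum(by_grp$observed),
               overall$eo_ratio, tolerance = 1e-12)
})

test_that("bootstrap E/O intervals are seed-deterministic with degenerate b = 1", {
  set.seed(12)
  n <- 200
  wid <- rep(sprintf("W%03d", 1:100), each = 2)
  preds <- runif(n, 0, 0.4)
  outc <- ifelse(runif(n) < 0.2, "advanced_cancer", "none")

  ci1 <- bootstrap_eo_ci(wid, preds, outc, b = 1, seed = 5)
  expect_equal(ci1$eo_low, ci1$eo_high)

  ci2 <- bootstrap_eo_ci(wid, preds, outc, b = 50, seed = 9)
  ci3 <- bootstrap_eo_ci(wid, preds, outc, b = 50, seed = 9)
  expect_identical(ci2, ci3)
  expect_lte(ci2$eo_low, ci2$eo_high)
})

test_that("bootstrap E/O intervals cover 1.0 at roughly nominal rate", {
  covered <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    sim <- test_cohort(n_women = 2500, seed = 1000 + r)
    rec <- sim$complete
    fit <- fit_round_models(rec, model_spec(TRUE))
    pred <- predict_round_risk(fit, rec, "advanced")
    ci <- bootstrap_eo_ci(rec$woman_id, pred, rec$outcome, b = 200,
                          seed = r)
    if (ci$eo_low <= 1 && ci$eo_high >= 1) covered <- covered + 1
  }
  # In-sample E/O is centred at 1 by the score identity; percentile
  # intervals should cover 1 at close to the nominal 95% rate.
  expect_gte(covered / reps, 0.85)
})

test_that("the Mann-Whitney AUC matches closed forms and an independent implementation", {
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_mann_whitney(c(0.3, 0.3), c(0, 1)), 0.5)
  expect_true(is.na(auc_mann_whitney(c(0.3, 0.4), c(1, 1))))

  set.seed(13)
  score <- runif(500)
  y <- rbinom(500, 1, plogis(3 * score - 2))
  a <- auc_mann_whitney(score, y)
  # Invariance under strictly monotone transforms.
  expect_equal(auc_mann_whitney(qlogis(score * 0.98 + 0.01), y), a)
  # Independent oracle.
  skip_if_not_installed("pROC")
  a_ref <- as.numeric(pROC::auc(pROC::roc(y, score, quiet = TRUE,
                                          direction = "<")))
  expect_equal(a, a_ref, tolerance = 1e-12)
})

test_that("cross-validated AUC partitions women and matches leave-one-woman-out brute force", {
  cc <- simple_conditionals()
  for (r in names(cc)) cc[[r]]$menopause <- c(pre = 0.5, post = 0.5)
  cfg <- generator_config(
    n_women = 120, seed = 61,
    interval_probs = c(annual = 0.5, biennial = 0.5),
    covariate_conditionals = cc,
    true_model = true_model(
      setNames(rep(qlogis(0.18), 4), stratum_labels()),
      c(age = 0, "density=heterogeneous" = 0.8, "density=extreme" = 1.0),
      setNames(rep(qlogis(0.3), 4), stratum_labels()),
      c(age = 0)
    )
  )
  sim <- simulate_cohort(cfg, mask = FALSE)
  rec <- sim$complete
  spec <- model_spec(FALSE)
  k <- length(unique(rec$woman_id))
  res <- cross_validated_auc(rec, spec, k = k, seed = 3, b_ci = 0)
  oof <- attr(res, "oof")

  brute <- numeric(nrow(rec))
  for (i in seq_len(nrow(rec))) {
    train <- rec$woman_id != rec$woman_id[i]
    fit <- fit_round_models(rec[train, ], spec)
    brute[i] <- predict_round_risk(fit, rec[i, ], "advanced")
  }
  expect_equal(oof, brute, tolerance = 1e-8)
  expect_equal(res$auc[res$group == "overall"],
               auc_mann_whitney(brute, rec$outcome == "advanced_cancer"),
               tolerance = 1e-12)
})

test_that("per-group AUCs and CIs are reported for race groups", {
  sim <- test_cohort(n_women = 4000, seed = 63)
  rec <- sim$complete
  res <- cross_validated_auc(rec, model_spec(TRUE), k = 5, seed = 2,
                             group_labels = rec$race_ethnicity, b_ci = 20)
  expect_true("overall" %in% res$group)
  ok <- res[res$estimable, ]
  expect_true(all(ok$auc >= 0 & ok$auc <= 1))
  expect_true(all(ok$auc_low <= ok$auc_high, na.rm = TRUE))
})
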