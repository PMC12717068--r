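test_that("cohort generation is seed-deterministic and honors degenerate distributions", {
  cfg <- generator_config(n_women = 1000, seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))

  one_race <- c("Asian" = 0, "Black" = 1, "Hispanic" = 0,
                "Other/Multiple" = 0, "White" = 0)
  cfg1 <- generator_config(n_women = 500, race_probs = one_race, seed = 3)
  expect_true(all(generate_cohort(cfg1)$race_ethnicity == "Black"))

  expect_error(generator_config(n_women = -5),
               class = "screenaudit_config_error")
  bad <- c("Asian" = 0.5, "Black" = 0.5, "Hispanic" = -0.2,
           "Other/Multiple" = 0.1, "White" = 0.1)
  expect_error(generator_config(race_probs = bad),
               class = "screenaudit_config_error")
})

test_that("covariate margins converge to configured probabilities", {
  cfg <- generator_config(n_women = 50000, seed = 19)
  rec <- generate_cohort(cfg)
  n <- nrow(rec)
  for (r in names(cfg$race_probs)) {
    p <- cfg$race_probs[[r]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(rec$race_ethnicity == r) - p), 3 * se)
  }
  p_ann <- cfg$interval_probs[["annual"]]
  expect_lt(abs(mean(rec$interval == "annual") - p_ann),
            3 * sqrt(p_ann * (1 - p_ann) / n))
  expect_true(all(rec$age >= 40 & rec$age <= 74))
  expect_true(all(is.na(rec$outcome)))
})

test_that("outcomes follow the inverse-logit generating law", {
  # Degenerate limit: deeply negative intercepts give no events at all.
  rec <- generate_cohort(generator_config(n_women = 2000, seed = 5))
  null_model <- true_model(
    setNames(rep(-50, 4), stratum_labels()), c(age = 0),
    setNames(rep(-50, 4), stratum_labels()), c(age = 0))
  out0 <- simulate_outcomes(rec, null_model, seed = 5)
  expect_true(all(out0$outcome == "none"))

  # Binomial oracle at logit(0.5): the advanced fraction is ~ Bin(n, 0.5).
  rec2 <- generate_cohort(generator_config(n_women = 50000, seed = 21))
  half <- true_model(
    setNames(rep(qlogis(0.5), 4), stratum_labels()), c(age = 0),
    setNames(rep(-50, 4), stratum_labels()), c(age = 0))
  out <- simulate_outcomes(rec2, half, seed = 21)
  frac <- mean(out$outcome == "advanced_cancer")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(out)))

  # Injected race log odds ratio is recovered empirically (2x2 oracle).
  sim <- test_cohort(n_women = 60000, seed = 23)
  rec3 <- sim$complete
  adv <- rec3$outcome == "advanced_cancer"
  tab <- table(rec3$race_ethnicity == "Black", adv)
  log_or <- log(tab[2, 2] * tab[1, 1] / (tab[2, 1] * tab[1, 2]))
  se <- sqrt(sum(1 / tab))
  expect_lt(abs(log_or - log(2)), 3 * se)
})

test_that("missingness masking honors rates and leaves other fields intact", {
  sim <- test_cohort(n_women = 5000, seed = 9)
  rec <- sim$complete
  rates0 <- setNames(rep(0, 6), maskable_variables())
  expect_identical(apply_missingness(rec, rates0, seed = 1), rec)

  rates1 <- c(bmi = 1)
  m1 <- apply_missingness(rec, rates1, seed = 1)
  expect_true(all(is.na(m1$bmi)))
  expect_identical(m1$density, rec$density)
  expect_identical(m1$outcome, rec$outcome)

  rates <- c(bmi = 0.35)
  mm <- apply_missingness(rec, rates, seed = 2)
  expect_equal(nrow(mm), nrow(rec))
  frac <- mean(is.na(mm$bmi))
  expect_lt(abs(frac - 0.35), 3 * sqrt(0.35 * 0.65 / nrow(rec)))
  # Unmasked entries are preserved.
  expect_identical(mm$bmi[!is.na(mm$bmi)], rec$bmi[!is.na(mm$bmi)])
  expect_error(apply_missingness(rec, c(bmi = 1.4)),
               class = "screenaudit_config_error")

  # MAR switch: missingness increases with age.
  mar <- setNames(c(rep(FALSE, 5), TRUE), maskable_variables())
  names(mar) <- maskable_variables()
  mar[] <- FALSE; mar["bmi"] <- TRUE
  mmar <- apply_missingness(rec, c(bmi = 0.35), seed = 3, mar = mar)
  young <- mean(is.na(mmar$bmi[rec$age < 50]))
  old <- mean(is.na(mmar$bmi[rec$age >= 65]))
  expect_gt(old, young)
})

test_that("characteristics table reproduces published count arithmetic", {
  counts <- published_counts()
  tab <- summarize_characteristics(counts = counts)
  pick <- function(iv, lvl) {
    tab$row_pct[tab$interval == iv & tab$level == lvl]
  }
  expect_equal(pick("annual", "Black"), 0.08)
  expect_equal(pick("annual", "Asian"), 0.03)
  expect_equal(pick("biennial", "Black"), 0.16)
  expect_equal(pick("annual", "White"), 0.04)
  # Column percentages agree with the published column layout.
  colpick <- function(iv, lvl, col) {
    tab[[col]][tab$interval == iv & tab$level == lvl]
  }
  expect_equal(colpick("annual", "Asian", "col_pct_no_advanced"), 9.4)
  expect_equal(colpick("annual", "Asian", "col_pct_advanced"), 6.5)
  expect_equal(colpick("annual", "Black", "col_pct_advanced"), 17.3)

  # Zero numerator reports 0.00, not NaN.
  zero <- summarize_characteristics(counts = tibble::tibble(
    interval = "annual", variable = "race_ethnicity", level = "Asian",
    n_advanced = 0, n_no_advanced = 10))
  expect_equal(zero$row_pct, 0)
})

test_that("characteristics table from records matches direct tabulation", {
  sim <- test_cohort(n_women = 3000, seed = 13)
  rec <- sim$complete
  tab <- summarize_characteristics(rec)
  sel <- tab$variable == "race_ethnicity" & tab$interval == "annual" &
    tab$level == "Black"
  expected_adv <- sum(rec$outcome == "advanced_cancer" &
                        rec$interval == "annual" &
                        rec$race_ethnicity == "Black")
  expect_equal(tab$n_advanced[sel], expected_adv)
  n_no <- tab$n_no_advanced[sel]
  expect_equal(tab$row_pct[sel],
               round(100 * expected_adv / (expected_adv + n_no), 2),
               tolerance = 0.006)
})

test_that("reference population and reweighting identities hold", {
  sim <- test_cohort(n_women = 4000, seed = 17)
  rec <- sim$complete
  ref <- make_reference_population(rec)
  expect_equal(sum(ref$proportion), 1, tolerance = 1e-12)
  w <- compute_weights(rec, ref)
  expect_equal(w$weight, rep(1, nrow(rec)), tolerance = 1e-12)

  # Perturbed reference: weighted race margins equal the reference margins.
  pert <- ref
  pert$proportion <- pert$proportion *
    ifelse(pert$race_ethnicity == "Black", 2, 1)
  pert <- make_reference_population(type = "supplied", proportions = pert)
  w2 <- compute_weights(rec, pert)
  got <- tapply(w2$weight, rec$race_ethnicity, sum) / sum(w2$weight)
  want <- tapply(pert$proportion, pert$race_ethnicity, sum)
  expect_equal(as.numeric(got[names(want)]), as.numeric(want),
               tolerance = 1e-9)

  expect_error(make_reference_population(rec[0, ]),
               class = "screenaudit_config_error")
})
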