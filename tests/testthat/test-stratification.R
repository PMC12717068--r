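# Brute-force oracle: scan the weighted CDF for the smallest value whose
# cumulative normalized weight reaches p.
scan_quantile <- function(x, w, p) {
  ord <- order(x)
  cw <- cumsum(w[ord]) / sum(w)
  for (i in seq_along(ord)) {
    if (cw[i] >= p - 1e-12) return(x[ord[i]])
  }
  x[ord[length(ord)]]
}

test_that("weighted percentiles match grid, point-mass and scan oracles", {
  thr <- compute_thresholds(1:100, variant = "include_race")
  expect_equal(c(thr$t5, thr$t25, thr$t75, thr$t95), c(5, 25, 75, 95))

  # A weight-dominant observation pins every cut point to its risk.
  thr2 <- compute_thresholds(c(0.4, 1.2, 3), c(1e9, 1, 1))
  expect_equal(c(thr2$t5, thr2$t25, thr2$t75, thr2$t95), rep(0.4, 4))

  set.seed(21)
  for (i in 1:10) {
    x <- runif(200) * 10
    w <- rexp(200) + 0.01
    for (p in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
      expect_equal(weighted_quantile(x, w, p), scan_quantile(x, w, p))
    }
  }
  expect_warning(compute_thresholds(rep(2, 5)), "degenerate")
})

test_that("category assignment respects the published boundary rules", {
  # Published include-race thresholds: high > 0.658, intermediate > 0.380,
  # average > 0.172, low > 0.090 (6-year cumulative risk, %).
  thr <- structure(list(variant = "include_race", t5 = 0.090, t25 = 0.172,
                        t75 = 0.380, t95 = 0.658),
                   class = "risk_thresholds")
  expect_equal(as.character(assign_category(0.700, thr)), "high")
  expect_equal(as.character(assign_category(0.658, thr)), "intermediate")
  expect_equal(as.character(assign_category(0.380, thr)), "average")
  expect_equal(as.character(assign_category(0, thr)), "very low")
  expect_equal(as.character(assign_category(0.100, thr)), "low")
})

test_that("thresholds applied to their defining sample give 5/20/50/20/5", {
  set.seed(23)
  n <- 4000
  risks_inc <- rlnorm(n, -1, 0.8)
  risks_exc <- risks_inc * exp(rnorm(n, 0, 0.3))
  race <- sample(race_levels(), n, replace = TRUE)
  prev <- category_prevalence(
    list(include_race = risks_inc, exclude_race = risks_exc),
    race_labels = race
  )
  overall <- prev[prev$race == "overall" & prev$variant != "difference", ]
  want <- c("very low" = 5, "low" = 20, "average" = 50,
            "intermediate" = 20, "high" = 5)
  for (v in c("include_race", "exclude_race")) {
    got <- overall$weighted_pct[overall$variant == v]
    names(got) <- as.character(overall$category[overall$variant == v])
    expect_equal(got[names(want)], want, tolerance = 0.001)
  }
  # Categories partition: percentages sum to 100 within each variant x race.
  sums <- prev |>
    dplyr::filter(.data$variant != "difference") |>
    dplyr::group_by(.data$variant, .data$race) |>
    dplyr::summarise(s = sum(.data$weighted_pct), .groups = "drop")
  expect_true(all(abs(sums$s - 100) < 0.1))
  # Difference rows are exclude minus include.
  d <- prev[prev$variant == "difference" & prev$race == "overall", ]
  i <- prev[prev$variant == "include_race" & prev$race == "overall", ]
  e <- prev[prev$variant == "exclude_race" & prev$race == "overall", ]
  expect_equal(d$weighted_pct, e$weighted_pct - i$weighted_pct)
})

test_that("weighted medians and IQRs match small-set and scan oracles", {
  res <- median_iqr_by_status(c(1, 2, 3), rep("a", 3), rep(FALSE, 3))
  expect_equal(res$median, 2)
  expect_equal(res$q25, 1)
  expect_equal(res$q75, 3)

  res2 <- median_iqr_by_status(rep(4, 5), rep("a", 5), rep(TRUE, 5))
  expect_equal(c(res2$median, res2$q25, res2$q75), rep(4, 3))

  set.seed(25)
  x <- runif(150); w <- rexp(150) + 0.1
  res3 <- median_iqr_by_status(x, rep("a", 150), rep(FALSE, 150),
                               weights = w)
  expect_equal(res3$median, scan_quantile(x, w, 0.5))
  expect_equal(res3$q25, scan_quantile(x, w, 0.25))
  expect_equal(res3$q75, scan_quantile(x, w, 0.75))
})

test_that("model comparison reports reclassification deltas", {
  thr <- compute_thresholds(1:100, variant = "include_race")
  risks <- c(80, 85, 96, 10)
  race <- c("Black", "Black", "Asian", "Asian")
  status <- c(TRUE, FALSE, TRUE, FALSE)
  s1 <- intermediate_high_share(risks, thr, race, status)
  s2 <- intermediate_high_share(risks, thr, race, status)
  cmp <- compare_models(s1, s2)
  expect_true(all(cmp$delta == 0))

  # One woman crossing t75 under the second model moves her whole cell.
  risks2 <- risks; risks2[1] <- 60
  s3 <- intermediate_high_share(risks2, thr, race, status)
  cmp2 <- compare_models(s1, s3)
  expect_equal(cmp2$delta[cmp2$race == "Black" & cmp2$status == "advanced"],
               -100)
  expect_true(all(cmp2$delta[cmp2$race == "Asian"] == 0))

  # Misaligned summaries are a contract error.
  expect_error(compare_models(s1, s3[-1, ]),
               class = "screenaudit_contract_error")
})
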