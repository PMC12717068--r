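# Shared fixtures: all cohorts are generated in code at test time.

# A compact cohort with elevated baseline rates so that small test cohorts
# still contain events in every menopause x interval stratum.
test_true_model <- function(base_annual = 0.03, race_black = log(2),
                            race_asian = log(0.7)) {
  adv_int <- c("pre.annual" = qlogis(base_annual),
               "post.annual" = qlogis(base_annual * 1.25),
               "pre.biennial" = qlogis(base_annual * 2),
               "post.biennial" = qlogis(base_annual * 2.5))
  adv_coef <- c(age = 0, age_sq = 0,
                "race_ethnicity=Black" = race_black,
                "race_ethnicity=Asian" = race_asian,
                "family_history=yes" = log(1.4),
                "density=heterogeneous" = 0.5,
                "density=extreme" = 0.7)
  cmp_int <- c("pre.annual" = qlogis(0.015), "post.annual" = qlogis(0.02),
               "pre.biennial" = qlogis(0.04),
               "post.biennial" = qlogis(0.05))
  cmp_coef <- c(age = 0, age_sq = 0, "bmi=obese-II/III" = 0.3)
  true_model(adv_int, adv_coef, cmp_int, cmp_coef)
}

# Covariate conditionals without very rare levels, so tiny strata do not run
# into empty design columns.
simple_conditionals <- function() {
  cc <- default_covariate_conditionals()
  for (r in names(cc)) {
    cc[[r]]$biopsy_history <- c("none" = 0.7, "benign-unknown" = 0.15,
                                "non-proliferative" = 0.08,
                                "proliferative-no-atypia" = 0.05,
                                "proliferative-atypia" = 0.02)
    cc[[r]]$bmi <- c(underweight = 0.05, normal = 0.4, overweight = 0.3,
                     "obese-I" = 0.15, "obese-II/III" = 0.1)
  }
  cc
}

test_config <- function(n_women = 2000, seed = 7, ...) {
  generator_config(n_women = n_women, seed = seed,
                   covariate_conditionals = simple_conditionals(),
                   true_model = test_true_model(), ...)
}

test_cohort <- function(n_women = 2000, seed = 7, mask = FALSE, ...) {
  simulate_cohort(test_config(n_women = n_women, seed = seed, ...),
                  mask = mask)
}

published_counts <- function() {
  readr::read_csv(
    system.file("extdata", "published_race_counts.csv",
                package = "screenaudit"),
    show_col_types = FALSE
  )
}

published_totals <- function() {
  readr::read_csv(
    system.file("extdata", "published_screen_totals.csv",
                package = "screenaudit"),
    show_col_types = FALSE
  )
}
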