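#' Specify the data-generating outcome model for synthetic cohorts
#'
#' The generator draws per-exam outcomes from a pair of logistic models: one
#' for advanced breast cancer within the screening follow-up window, and one
#' for a competing event (death or early-stage cancer) conditional on no
#' advanced cancer in the same window. Each model has one intercept per
#' menopause-by-interval stratum and a shared coefficient vector over
#' covariates; categorical coefficients are named `"variable=level"` with
#' reference levels fixed at 0, and age enters through `"age"` and `"age_sq"`
#' terms on the raw year scale.
#'
#' @param advanced_intercepts Named log-odds, one per stratum
#'   (`"pre.annual"`, `"post.annual"`, `"pre.biennial"`, `"post.biennial"`).
#' @param advanced_coefficients Named log-odds vector for the advanced-cancer
#'   model.
#' @param competing_intercepts,competing_coefficients Same structure for the
#'   competing-event model.
#' @return An object of class `true_model`.
#' @seealso [default_true_model()] for the packaged defaults,
#'   [simulate_outcomes()] which inverts this model.
#' @export
true_model <- function(advanced_intercepts, advanced_coefficients,
                       competing_intercepts, competing_coefficients) {
  strata <- stratum_labels()
  for (ints in list(advanced_intercepts, competing_intercepts)) {
    if (!all(strata %in% names(ints))) {
      abort("Intercepts must be named for all four menopause x interval strata.",
            class = "screenaudit_model_error")
    }
    if (any(!is.finite(ints))) {
      abort("Intercepts must be finite log-odds.",
            class = "screenaudit_model_error")
    }
  }
  validate_coefficient_names(advanced_coefficients)
  validate_coefficient_names(competing_coefficients)
  structure(
    list(
      advanced_intercepts = advanced_intercepts[strata],
      advanced_coefficients = advanced_coefficients,
      competing_intercepts = competing_intercepts[strata],
      competing_coefficients = competing_coefficients
    ),
    class = "true_model"
  )
}

stratum_labels <- function() {
  c("pre.annual", "post.annual", "pre.biennial", "post.biennial")
}

stratum_of <- function(menopause, interval) {
  paste(menopause, interval, sep = ".")
}

validate_coefficient_names <- function(coefs) {
  lv <- covariate_level_list()
  for (nm in names(coefs)) {
    if (nm %in% c("age", "age_sq")) next
    parts <- strsplit(nm, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L || !parts[1L] %in% names(lv) ||
        !parts[2L] %in% lv[[parts[1L]]]) {
      abort(sprintf("Coefficient '%s' does not reference a known covariate level.",
                    nm),
            class = "screenaudit_model_error")
    }
  }
  invisible(coefs)
}

# Evaluate a true-model linear predictor for a set of complete records.
true_linear_predictor <- function(records, intercepts, coefs) {
  eta <- unname(intercepts[stratum_of(records$menopause, records$interval)])
  if ("age" %in% names(coefs)) eta <- eta + coefs[["age"]] * records$age
  if ("age_sq" %in% names(coefs)) eta <- eta + coefs[["age_sq"]] * records$age^2
  cat_terms <- setdiff(names(coefs), c("age", "age_sq"))
  for (nm in cat_terms) {
    parts <- strsplit(nm, "=", fixed = TRUE)[[1L]]
    eta <- eta + coefs[[nm]] * (records[[parts[1L]]] == parts[2L])
  }
  eta
}

# Centered-age helper: coefficients are easier to reason about around the
# cohort age midpoint; convert (b1, b2) on (age - c) to raw age / age^2
# terms, i.e. b0 + b1 (a-c) + b2 (a-c)^2 = (b0 - b1 c + b2 c^2)
#                                          + (b1 - 2 b2 c) a + b2 a^2.
raw_age_terms <- function(b1, b2, center = 57) {
  c(age = b1 - 2 * b2 * center, age_sq = b2)
}

centered_intercept_shift <- function(b1, b2, center = 57) {
  -b1 * center + b2 * center^2
}

#' Default data-generating model for synthetic screening cohorts
#'
#' Race and ethnicity effects follow the published per-exam advanced-cancer
#' rate ratios for screened women (about twofold elevation for Black women and
#' about 0.7-fold for Asian women relative to White women); family history,
#' benign biopsy history, breast density and BMI effects are graded in the
#' directions seen in screening cohorts. Baseline per-round advanced-cancer
#' probabilities default to roughly ten times the real-world per-exam
#' magnitudes (about 0.4--1\% per round at the reference profile) so that
#' desk-scale cohorts contain enough events for stable model fitting;
#' `realistic_rates = TRUE` restores the real-world 0.03--0.16\% order of
#' magnitude. Competing events (death or early-stage cancer) run at roughly
#' 1\% per annual round and 2\% per biennial round and are not inflated.
#'
#' @param realistic_rates If `TRUE`, use real-world advanced-cancer baseline
#'   rates instead of the inflated desk-scale defaults.
#' @return A [true_model()] object.
#' @export
default_true_model <- function(realistic_rates = FALSE) {
  rate_shift <- if (realistic_rates) log(10) else 0
  adv_age <- raw_age_terms(0.03, -5e-4)
  adv_shift <- centered_intercept_shift(0.03, -5e-4)
  adv_int <- c(
    "pre.annual" = qlogis(0.004), "post.annual" = qlogis(0.005),
    "pre.biennial" = qlogis(0.008), "post.biennial" = qlogis(0.010)
  ) - rate_shift + adv_shift
  adv_coef <- c(
    adv_age,
    "race_ethnicity=Asian" = log(0.7),
    "race_ethnicity=Black" = log(2.0),
    "race_ethnicity=Hispanic" = 0,
    "race_ethnicity=Other/Multiple" = log(1.2),
    "family_history=yes" = log(1.4),
    "biopsy_history=benign-unknown" = 0.45,
    "biopsy_history=non-proliferative" = 0.35,
    "biopsy_history=proliferative-no-atypia" = 0.40,
    "biopsy_history=proliferative-atypia" = 0.75,
    "density=scattered" = 0.35,
    "density=heterogeneous" = 0.75,
    "density=extreme" = 0.90,
    "bmi=overweight" = 0.15,
    "bmi=obese-I" = 0.25,
    "bmi=obese-II/III" = 0.45
  )
  cmp_age <- raw_age_terms(0.05, 0)
  cmp_shift <- centered_intercept_shift(0.05, 0)
  cmp_int <- c(
    "pre.annual" = qlogis(0.008), "post.annual" = qlogis(0.012),
    "pre.biennial" = qlogis(0.016), "post.biennial" = qlogis(0.024)
  ) + cmp_shift
  cmp_coef <- c(
    cmp_age,
    "race_ethnicity=Asian" = -0.2,
    "race_ethnicity=Black" = 0.3,
    "family_history=yes" = 0.1,
    "density=scattered" = 0.1,
    "density=heterogeneous" = 0.2,
    "density=extreme" = 0.2,
    "bmi=underweight" = 0.3,
    "bmi=overweight" = 0.1,
    "bmi=obese-I" = 0.2,
    "bmi=obese-II/III" = 0.4
  )
  true_model(adv_int, adv_coef, cmp_int, cmp_coef)
}

default_covariate_conditionals <- function() {
  base <- list(
    age = list(min = 40, max = 74),
    menopause = c(pre = 0.303, post = 0.697),
    family_history = c(no = 0.818, yes = 0.182),
    biopsy_history = c("none" = 0.766, "benign-unknown" = 0.153,
                       "non-proliferative" = 0.056,
                       "proliferative-no-atypia" = 0.021,
                       "proliferative-atypia" = 0.004),
    density = c(fatty = 0.095, scattered = 0.428,
                heterogeneous = 0.393, extreme = 0.084),
    bmi = c(underweight = 0.015, normal = 0.426, overweight = 0.293,
            "obese-I" = 0.153, "obese-II/III" = 0.113)
  )
  norm <- function(p) p / sum(p)
  base[-1L] <- lapply(base[-1L], norm)
  out <- setNames(rep(list(base), length(race_levels())), race_levels())
  # Race-specific departures: Asian women denser and leaner; Black women less
  # dense and heavier, mirroring screening-cohort covariate contrasts.
  out[["Asian"]]$density <- norm(c(fatty = 0.05, scattered = 0.32,
                                   heterogeneous = 0.48, extreme = 0.15))
  out[["Asian"]]$bmi <- norm(c(underweight = 0.03, normal = 0.60,
                               overweight = 0.25, "obese-I" = 0.08,
                               "obese-II/III" = 0.04))
  out[["Black"]]$density <- norm(c(fatty = 0.13, scattered = 0.47,
                                   heterogeneous = 0.33, extreme = 0.07))
  out[["Black"]]$bmi <- norm(c(underweight = 0.01, normal = 0.25,
                               overweight = 0.28, "obese-I" = 0.24,
                               "obese-II/III" = 0.22))
  out
}

default_missingness_rates <- function() {
  c(race_ethnicity = 0.045, menopause = 0.18, family_history = 0.038,
    biopsy_history = 0, density = 0.02, bmi = 0.35)
}

#' Configure the synthetic screening-cohort generator
#'
#' Defaults emulate the covariate structure of a large U.S. screening
#' mammography cohort: five race and ethnicity groups with distinct density
#' and BMI distributions, a 77/23 annual/biennial split, ages uniform over
#' 40--74, and item-level missingness concentrated in BMI (about 35\%) and
#' menopausal status (about 18\%).
#'
#' @param n_women Number of women.
#' @param interval_probs Named probabilities for `annual` / `biennial`.
#' @param race_probs Named probabilities over [race_levels()].
#' @param covariate_conditionals Per-race list of covariate distributions; see
#'   the package vignette. Defaults to [default_covariate_conditionals()].
#' @param true_model A [true_model()]; defaults to
#'   `default_true_model(realistic_rates)`.
#' @param missingness_rates Named per-variable masking probabilities over
#'   [maskable_variables()].
#' @param mar Named logical switches: when `TRUE` for a variable, its
#'   missingness probability depends logistically on age and interval
#'   (missing-at-random) instead of being uniform (MCAR).
#' @param rounds_observed Screening rounds emitted per woman (default 1; the
#'   screening exam is the unit of analysis).
#' @param realistic_rates Passed to [default_true_model()] when no model is
#'   supplied.
#' @param seed Integer seed; the same configuration and seed reproduce the
#'   cohort byte for byte.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_women = 10000,
                             interval_probs = c(annual = 0.772,
                                                biennial = 0.228),
                             race_probs = c("Asian" = 0.0985,
                                            "Black" = 0.0943,
                                            "Hispanic" = 0.0482,
                                            "Other/Multiple" = 0.0178,
                                            "White" = 0.7412),
                             covariate_conditionals =
                               default_covariate_conditionals(),
                             true_model = NULL,
                             missingness_rates = default_missingness_rates(),
                             mar = NULL,
                             rounds_observed = 1,
                             realistic_rates = FALSE,
                             seed = 1) {
  n_women <- as_count(n_women, "n_women")
  rounds_observed <- as_count(rounds_observed, "rounds_observed")
  interval_probs <- interval_probs / sum(interval_probs)
  race_probs <- race_probs / sum(race_probs)
  check_prob_block(interval_probs, "interval_probs")
  check_prob_block(race_probs, "race_probs")
  if (!setequal(names(race_probs), race_levels())) {
    abort("race_probs must be named with exactly the five race levels.",
          class = "screenaudit_config_error")
  }
  if (!setequal(names(covariate_conditionals), race_levels())) {
    abort("covariate_conditionals must supply one block per race level.",
          class = "screenaudit_config_error")
  }
  lv <- covariate_level_list()
  for (race in names(covariate_conditionals)) {
    blk <- covariate_conditionals[[race]]
    if (blk$age$min < 40 || blk$age$max > 74 || blk$age$min >= blk$age$max) {
      abort(sprintf("Age support for '%s' must lie within [40, 74].", race),
            class = "screenaudit_config_error")
    }
    for (v in c("menopause", "family_history", "biopsy_history",
                "density", "bmi")) {
      key <- if (v == "biopsy_history") "biopsy_history" else v
      p <- blk[[key]]
      check_prob_block(p, paste0(race, "$", v))
      want <- lv[[if (v == "biopsy_history") "biopsy_history" else v]]
      if (!setequal(names(p), want)) {
        abort(sprintf("Block '%s$%s' must be named with its full level set.",
                      race, v),
              class = "screenaudit_config_error")
      }
    }
  }
  if (is.null(true_model)) true_model <- default_true_model(realistic_rates)
  stopifnot(inherits(true_model, "true_model"))
  vars <- maskable_variables()
  missingness_rates <- missingness_rates[vars]
  names(missingness_rates) <- vars
  missingness_rates[is.na(missingness_rates)] <- 0
  if (any(missingness_rates < 0 | missingness_rates > 1)) {
    abort("missingness_rates must lie in [0, 1].",
          class = "screenaudit_config_error")
  }
  if (is.null(mar)) mar <- setNames(rep(FALSE, length(vars)), vars)
  structure(
    list(n_women = n_women, interval_probs = interval_probs,
         race_probs = race_probs,
         covariate_conditionals = covariate_conditionals,
         true_model = true_model, missingness_rates = missingness_rates,
         mar = mar, rounds_observed = rounds_observed,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generate a synthetic screening cohort (covariates only)
#'
#' Emits one row per screening exam (`n_women * rounds_observed` rows) with
#' complete covariates and `outcome = NA`; outcomes are drawn separately by
#' [simulate_outcomes()] and missingness applied by [apply_missingness()], so
#' the complete pre-masking cohort stays available as an oracle.
#'
#' @param config A [generator_config()].
#' @return A tibble of screening-exam records. Ages are reported in years to
#'   0.1 precision; within a woman, age advances by the interval length per
#'   round.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(derive_seed(config$seed, "cohort"), {
    n <- config$n_women
    interval <- sample(names(config$interval_probs), n, replace = TRUE,
                       prob = config$interval_probs)
    race <- sample(names(config$race_probs), n, replace = TRUE,
                   prob = config$race_probs)
    draw_for <- function(var) {
      out <- character(n)
      for (r in race_levels()) {
        idx <- which(race == r)
        if (!length(idx)) next
        p <- config$covariate_conditionals[[r]][[var]]
        out[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
      }
      out
    }
    age <- numeric(n)
    for (r in race_levels()) {
      idx <- which(race == r)
      if (!length(idx)) next
      supp <- config$covariate_conditionals[[r]]$age
      age[idx] <- runif(length(idx), supp$min, supp$max)
    }
    women <- tibble::tibble(
      woman_id = sprintf("W%07d", seq_len(n)),
      interval = interval,
      age = round(age, 1),
      race_ethnicity = race,
      menopause = draw_for("menopause"),
      family_history = draw_for("family_history"),
      biopsy_history = draw_for("biopsy_history"),
      density = draw_for("density"),
      bmi = draw_for("bmi")
    )
    step <- ifelse(women$interval == "annual", 1, 2)
    out <- purrr::map_dfr(seq_len(config$rounds_observed), function(k) {
      dplyr::mutate(women,
                    round_index = k,
                    age = round(.data$age + step * (k - 1L), 1))
    })
    dplyr::arrange(
      dplyr::mutate(out, outcome = NA_character_),
      .data$woman_id, .data$round_index
    ) |>
      dplyr::relocate("woman_id", "round_index", "interval", "age")
  })
}

#' Draw per-exam outcomes from a data-generating model
#'
#' For each exam, the advanced-cancer probability `q` is the inverse logit of
#' the advanced linear predictor and the competing-event probability `c`
#' (conditional on no advanced cancer) is the inverse logit of the competing
#' linear predictor. The outcome is advanced cancer with probability `q`,
#' otherwise a competing event with probability `(1 - q) * c`, otherwise none.
#'
#' @param records Exam records with complete covariates.
#' @param true_model A [true_model()].
#' @param seed Integer seed.
#' @return `records` with the `outcome` column filled.
#' @export
simulate_outcomes <- function(records, true_model, seed = 1) {
  stopifnot(inherits(true_model, "true_model"))
  needed <- c("age", "interval", maskable_variables())
  if (anyNA(records[needed])) {
    abort("simulate_outcomes() requires complete covariates.",
          class = "screenaudit_model_error")
  }
  q <- inv_logit(true_linear_predictor(records,
                                       true_model$advanced_intercepts,
                                       true_model$advanced_coefficients))
  cc <- inv_logit(true_linear_predictor(records,
                                        true_model$competing_intercepts,
                                        true_model$competing_coefficients))
  with_seed(derive_seed(seed, "outcomes"), {
    u1 <- runif(nrow(records))
    u2 <- runif(nrow(records))
    records$outcome <- ifelse(u1 < q, "advanced_cancer",
                              ifelse(u2 < cc, "competing_event", "none"))
  })
  records
}

#' Mask covariates to emulate item-level missingness
#'
#' Each maskable covariate is masked independently at its configured rate
#' (MCAR), or — when its `mar` switch is on — with a logistic dependence on
#' age and screening interval calibrated so the rate holds at the cohort age
#' midpoint for annual screeners. Outcome and interval are never masked.
#'
#' @param records Exam records.
#' @param rates Named rates over [maskable_variables()]; missing names mean 0.
#' @param seed Integer seed.
#' @param mar Named logical MAR switches (default all MCAR).
#' @return `records` with masked entries set to `NA`.
#' @export
apply_missingness <- function(records, rates, seed = 1, mar = NULL) {
  vars <- maskable_variables()
  rates <- rates[vars]
  names(rates) <- vars
  rates[is.na(rates)] <- 0
  if (any(rates < 0 | rates > 1)) {
    abort("Missingness rates must lie in [0, 1].",
          class = "screenaudit_config_error")
  }
  if (is.null(mar)) mar <- setNames(rep(FALSE, length(vars)), vars)
  with_seed(derive_seed(seed, "missingness"), {
    for (v in vars) {
      r <- rates[[v]]
      if (r == 0) next
      if (r == 1) {
        records[[v]] <- NA_character_
        next
      }
      p <- if (isTRUE(mar[[v]])) {
        inv_logit(qlogis(r) + 0.03 * (records$age - 57) +
                    0.3 * (records$interval == "biennial"))
      } else {
        r
      }
      mask <- runif(nrow(records)) < p
      records[[v]][mask] <- NA_character_
    }
  })
  records
}

#' Build a reference population table for direct standardization
#'
#' The standardization cells are age group (40-49, 50-59, 60-69, 70-74) by
#' race and ethnicity by first-degree family history. With `type = "cohort"`
#' the table is the cohort's own empirical cell distribution, so downstream
#' weights are all 1; a supplied table (`type = "supplied"`) is validated and
#' renormalized.
#'
#' @param records Complete exam records (used when `type = "cohort"`).
#' @param type `"cohort"` or `"supplied"`.
#' @param proportions For `type = "supplied"`: a data frame with columns
#'   `age_group`, `race_ethnicity`, `family_history`, `proportion`.
#' @return A tibble of class `reference_population`.
#' @export
make_reference_population <- function(records = NULL, type = c("cohort",
                                                               "supplied"),
                                      proportions = NULL) {
  type <- match.arg(type)
  if (type == "cohort") {
    if (is.null(records) || nrow(records) == 0L) {
      abort("make_reference_population(type = 'cohort') needs records.",
            class = "screenaudit_config_error")
    }
    if (anyNA(records[c("race_ethnicity", "family_history")])) {
      abort("Reference cells require complete race and family history.",
            class = "screenaudit_config_error")
    }
    tab <- records |>
      dplyr::mutate(age_group = as.character(age_group_of(.data$age))) |>
      dplyr::count(.data$age_group, .data$race_ethnicity,
                   .data$family_history, name = "n") |>
      dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
      dplyr::select(-"n")
  } else {
    if (is.null(proportions) || nrow(proportions) == 0L) {
      abort("make_reference_population(type = 'supplied') needs proportions.",
            class = "screenaudit_config_error")
    }
    tab <- tibble::as_tibble(proportions)
    stopifnot(all(c("age_group", "race_ethnicity", "family_history",
                    "proportion") %in% names(tab)))
    if (any(tab$proportion < 0)) {
      abort("Reference proportions must be nonnegative.",
            class = "screenaudit_config_error")
    }
    tab$proportion <- tab$proportion / sum(tab$proportion)
  }
  structure(tab, class = c("reference_population", class(tab)))
}

#' Tabulate cohort characteristics by interval and outcome status
#'
#' Produces the standard screening-cohort characteristics layout: for each
#' screening interval and each covariate level, the count and column
#' percentage of exams without and with advanced cancer, and the row
#' percentage `100 * advanced / (advanced + non-advanced)` rounded to two
#' decimals. Exams without advanced cancer include those with competing
#' events. Missing covariate values are tabulated as `"Unknown"`.
#'
#' Pre-aggregated counts (e.g. a published table's printed margins) can be
#' supplied instead of records via `counts`, with columns `interval`,
#' `variable`, `level`, `n_advanced`, `n_no_advanced`.
#'
#' @param records Exam records (ignored when `counts` is given).
#' @param counts Optional pre-aggregated counts.
#' @return A tibble with columns `interval`, `variable`, `level`,
#'   `n_no_advanced`, `col_pct_no_advanced`, `n_advanced`, `col_pct_advanced`,
#'   `row_pct`.
#' @export
summarize_characteristics <- function(records = NULL, counts = NULL) {
  if (is.null(counts)) {
    stopifnot(!is.null(records))
    vars <- c("age_group", maskable_variables())
    recs <- dplyr::mutate(records,
                          age_group = as.character(age_group_of(.data$age)),
                          advanced = .data$outcome == "advanced_cancer")
    counts <- purrr::map_dfr(vars, function(v) {
      recs |>
        dplyr::mutate(level = dplyr::coalesce(.data[[v]], "Unknown")) |>
        dplyr::group_by(.data$interval, .data$level) |>
        dplyr::summarise(
          n_advanced = sum(.data$advanced),
          n_no_advanced = sum(!.data$advanced),
          .groups = "drop"
        ) |>
        dplyr::mutate(variable = v)
    })
  } else {
    counts <- tibble::as_tibble(counts)
    stopifnot(all(c("interval", "variable", "level", "n_advanced",
                    "n_no_advanced") %in% names(counts)))
  }
  counts |>
    dplyr::group_by(.data$interval, .data$variable) |>
    dplyr::mutate(
      col_pct_no_advanced =
        round_half_up(100 * .data$n_no_advanced / sum(.data$n_no_advanced), 1),
      col_pct_advanced =
        round_half_up(100 * .data$n_advanced / sum(.data$n_advanced), 1),
      row_pct = round_half_up(
        100 * .data$n_advanced / (.data$n_advanced + .data$n_no_advanced), 2)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("interval", "variable", "level", "n_no_advanced",
                  "col_pct_no_advanced", "n_advanced", "col_pct_advanced",
                  "row_pct")
}

#' Generate a complete synthetic cohort with outcomes and missingness
#'
#' Convenience wrapper chaining [generate_cohort()], [simulate_outcomes()]
#' and (optionally) [apply_missingness()] under the configuration's seed.
#'
#' @param config A [generator_config()].
#' @param mask Apply the configured missingness (default `TRUE`).
#' @return A list with `records` (the analysis cohort), `complete` (the
#'   pre-masking cohort, an oracle for imputation checks) and `config`.
#' @export
simulate_cohort <- function(config, mask = TRUE) {
  complete <- simulate_outcomes(generate_cohort(config), config$true_model,
                                seed = config$seed)
  records <- if (mask && any(config$missingness_rates > 0)) {
    apply_missingness(complete, config$missingness_rates, seed = config$seed,
                      mar = config$mar)
  } else {
    complete
  }
  list(records = records, complete = complete, config = config)
}
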