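#' Advance a risk profile to a later screening round
#'
#' Between successive screens, age increases by the interval length (1 year
#' for annual, 2 for biennial); every other covariate, including the
#' menopause stratum, is held at its baseline value.
#'
#' @param profile Data frame of risk profiles with `age` and `interval`.
#' @param round_index 1-based round; round 1 returns the profile unchanged.
#' @return The profile with ages advanced to round entry.
#' @export
advance_profile <- function(profile, round_index) {
  stopifnot(round_index >= 1)
  step <- ifelse(profile$interval == "annual", 1, 2)
  profile$age <- profile$age + step * (round_index - 1)
  profile
}

#' Compound per-round event probabilities into a cumulative risk
#'
#' The discrete-time cause-specific form: with advanced-cancer probability
#' `q_k` and competing-event probability `c_k` (conditional on no advanced
#' cancer) at round `k`, the cumulative risk over `K` rounds is
#' `sum_k q_k * prod_{j<k} (1 - q_j) (1 - c_j)` — advanced cancer is
#' evaluated before the competing event within each round, and per-round
#' event-free survival is `(1 - q_j)(1 - c_j)`.
#'
#' @param q Numeric vector of per-round advanced-cancer probabilities.
#' @param c Numeric vector (same length) of per-round competing-event
#'   probabilities conditional on no advanced cancer.
#' @return The cumulative advanced-cancer risk, a probability.
#' @export
#' @examples
#' compound_round_risks(rep(0.001, 6), rep(0, 6)) # 1 - 0.999^6
compound_round_risks <- function(q, c = rep(0, length(q))) {
  stopifnot(length(q) == length(c), all(q >= 0), all(c >= 0))
  if (any(q >= 1 | c >= 1) || any(q + (1 - q) * c >= 1)) {
    abort("Per-round event probabilities imply total probability >= 1.",
          class = "screenaudit_contract_error")
  }
  surv <- 1
  risk <- 0
  for (k in seq_along(q)) {
    risk <- risk + surv * q[k]
    surv <- surv * (1 - q[k]) * (1 - c[k])
  }
  risk
}

#' Cumulative 6-year advanced breast cancer risk for risk profiles
#'
#' Compounds fitted per-round probabilities across the 6-year horizon — six
#' rounds for annual screeners, three for biennial — under competing risks.
#' At each round the profile's age is advanced by the interval length and the
#' round's advanced and competing probabilities are predicted from the fitted
#' models; with multiply imputed fits, predictions are pooled over
#' imputations round by round before compounding.
#'
#' @param profiles Data frame of fully observed risk profiles (covariates,
#'   `interval`, starting `age`).
#' @param fit A [fit_round_models()] result.
#' @param horizon Optional round counts overriding [horizon_rounds()].
#' @return `profiles` plus `variant`, `horizon_rounds`, `risk` (proportion)
#'   and `risk_pct` (percentage, rounded to 3 decimals).
#' @export
cumulative_risk <- function(profiles, fit, horizon = NULL) {
  stopifnot(inherits(fit, "round_model_fit"))
  n <- nrow(profiles)
  K <- horizon %||% horizon_rounds(profiles$interval)
  if (length(K) == 1L) K <- rep(K, n)
  surv <- rep(1, n)
  risk <- rep(0, n)
  for (k in seq_len(max(K))) {
    active <- which(K >= k)
    if (!length(active)) break
    prof_k <- advance_profile(profiles[active, , drop = FALSE], k)
    q <- predict_round_risk(fit, prof_k, "advanced")
    cc <- predict_round_risk(fit, prof_k, "competing")
    if (any(q + (1 - q) * cc >= 1)) {
      abort("Predicted per-round probabilities imply total probability >= 1.",
            class = "screenaudit_contract_error")
    }
    risk[active] <- risk[active] + surv[active] * q
    surv[active] <- surv[active] * (1 - q) * (1 - cc)
  }
  dplyr::mutate(tibble::as_tibble(profiles),
                variant = fit$variant,
                horizon_rounds = as.integer(K),
                risk = risk,
                risk_pct = round_half_up(100 * risk, 3))
}

#' Direct-standardization weights for a cohort
#'
#' Per-exam weight equal to the reference-population proportion of the exam's
#' age-group by race by family-history cell divided by the cohort's empirical
#' proportion of that cell. Applying the weights reweights the cohort's cell
#' distribution to the reference population; the same weights standardize
#' annual and biennial screeners to one population.
#'
#' @param records Complete exam records.
#' @param reference A [make_reference_population()] table.
#' @return Tibble with `woman_id`, the cell labels and `weight`, aligned
#'   row-for-row with `records`.
#' @export
compute_weights <- function(records, reference) {
  stopifnot(inherits(reference, "reference_population"))
  cells <- records |>
    dplyr::transmute(woman_id = .data$woman_id,
                     age_group = as.character(age_group_of(.data$age)),
                     race_ethnicity = .data$race_ethnicity,
                     family_history = .data$family_history)
  if (anyNA(cells)) {
    abort("compute_weights() requires complete age, race and family history.",
          class = "screenaudit_weighting_error")
  }
  emp <- cells |>
    dplyr::count(.data$age_group, .data$race_ethnicity, .data$family_history,
                 name = "n_cell") |>
    dplyr::mutate(cohort_prop = .data$n_cell / sum(.data$n_cell))
  joined <- dplyr::left_join(
    emp, tibble::as_tibble(reference),
    by = c("age_group", "race_ethnicity", "family_history")
  )
  if (anyNA(joined$proportion)) {
    missing_cells <- joined |>
      dplyr::filter(is.na(.data$proportion)) |>
      dplyr::mutate(cell = paste(.data$age_group, .data$race_ethnicity,
                                 .data$family_history, sep = " / "))
    abort(paste0("Reference population is missing populated cohort cells: ",
                 paste(missing_cells$cell, collapse = "; ")),
          class = "screenaudit_weighting_error")
  }
  joined <- dplyr::mutate(joined, weight = .data$proportion / .data$cohort_prop)
  dplyr::left_join(
    cells, dplyr::select(joined, "age_group", "race_ethnicity",
                         "family_history", "weight"),
    by = c("age_group", "race_ethnicity", "family_history")
  )
}
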