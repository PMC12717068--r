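# Canonical factor levels used throughout the package. Order is fixed so that
# encodings, model terms and serialized outputs are stable across runs.

race_levels <- function() {
  c("Asian", "Black", "Hispanic", "Other/Multiple", "White")
}

menopause_levels <- function() c("pre", "post")

family_history_levels <- function() c("no", "yes")

biopsy_levels <- function() {
  c("none", "benign-unknown", "non-proliferative",
    "proliferative-no-atypia", "proliferative-atypia")
}

density_levels <- function() c("fatty", "scattered", "heterogeneous", "extreme")

bmi_levels <- function() {
  c("underweight", "normal", "overweight", "obese-I", "obese-II/III")
}

interval_levels <- function() c("annual", "biennial")

outcome_levels <- function() c("none", "advanced_cancer", "competing_event")

# Covariates that can carry item-level missingness.
maskable_variables <- function() {
  c("race_ethnicity", "menopause", "family_history",
    "biopsy_history", "density", "bmi")
}

covariate_level_list <- function() {
  list(
    race_ethnicity = race_levels(),
    menopause = menopause_levels(),
    family_history = family_history_levels(),
    biopsy_history = biopsy_levels(),
    density = density_levels(),
    bmi = bmi_levels()
  )
}

# Age groups used for characteristics tables and standardization cells,
# matching the 40-49 / 50-59 / 60-69 / 70-74 reporting convention.
age_group_of <- function(age) {
  cut(age, breaks = c(40, 50, 60, 70, 75), right = FALSE,
      labels = c("40-49", "50-59", "60-69", "70-74"),
      include.lowest = TRUE)
}

#' Number of screening rounds in the 6-year horizon for an interval
#'
#' Six annual screens or three biennial screens span the 6-year horizon.
#'
#' @param interval Character vector of `"annual"` / `"biennial"`.
#' @return Integer vector of round counts.
#' @export
horizon_rounds <- function(interval) {
  ifelse(interval == "annual", 6L, 3L)
}
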