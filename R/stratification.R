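risk_category_levels <- function() {
  c("very low", "low", "average", "intermediate", "high")
}

#' Percentile risk thresholds from a weighted risk distribution
#'
#' Computes the 5th, 25th, 75th and 95th weighted percentiles of a variant's
#' cumulative-risk distribution (the combined annual + biennial sample),
#' using the left-continuous cumulative-weight rule of [weighted_quantile()].
#' Each model variant gets thresholds from its own risk distribution;
#' thresholds are never shared across variants.
#'
#' @param risks Cumulative 6-year risks (percentage or proportion scale —
#'   categories only require consistency with the risks later assigned).
#' @param weights Optional standardization weights.
#' @param variant Variant tag stored with the thresholds.
#' @return An object of class `risk_thresholds` with fields `t5`, `t25`,
#'   `t75`, `t95` and `variant`.
#' @export
compute_thresholds <- function(risks, weights = NULL,
                               variant = NA_character_) {
  if (!length(risks)) abort("compute_thresholds(): no risks supplied.",
                            class = "screenaudit_contract_error")
  if (!is.null(weights) && any(weights <= 0)) {
    abort("Weights must be strictly positive.",
          class = "screenaudit_contract_error")
  }
  qs <- weighted_quantile(risks, weights, c(0.05, 0.25, 0.75, 0.95))
  if (length(unique(risks)) == 1L) {
    warn("All risks identical; thresholds are degenerate.")
  }
  structure(list(variant = variant, t5 = qs[1L], t25 = qs[2L], t75 = qs[3L],
                 t95 = qs[4L]),
            class = "risk_thresholds")
}

#' @export
print.risk_thresholds <- function(x, ...) {
  cat(sprintf("<risk_thresholds> %s: t5=%.4g t25=%.4g t75=%.4g t95=%.4g\n",
              x$variant, x$t5, x$t25, x$t75, x$t95))
  invisible(x)
}

#' Assign five-level risk categories
#'
#' `high` above the 95th percentile threshold; `intermediate` above the 75th
#' up to and including the 95th; `average` above the 25th up to the 75th;
#' `low` above the 5th up to the 25th; `very low` at or below the 5th.
#' Boundaries are inclusive on the lower category (a risk exactly at a
#' threshold takes the lower category).
#'
#' @param risk Numeric risks on the thresholds' scale.
#' @param thresholds A [compute_thresholds()] object.
#' @return Factor over the five ordered category levels.
#' @export
assign_category <- function(risk, thresholds) {
  stopifnot(inherits(thresholds, "risk_thresholds"))
  out <- ifelse(risk > thresholds$t95, "high",
         ifelse(risk > thresholds$t75, "intermediate",
         ifelse(risk > thresholds$t25, "average",
         ifelse(risk > thresholds$t5, "low", "very low"))))
  factor(out, levels = risk_category_levels())
}

#' Weighted risk-category prevalence by race and model variant
#'
#' For each variant, assigns categories using that variant's thresholds and
#' tabulates the weighted percentage of women per category within each race
#' group and overall, plus the exclude-minus-include difference. Evaluated on
#' the threshold-defining sample itself, the overall prevalences are
#' 5/20/50/20/5 percent by construction (up to ties).
#'
#' @param risks_by_variant Named list with elements `include_race` and
#'   `exclude_race`: aligned risk vectors for the same women.
#' @param weights Optional positive weights (default equal).
#' @param race_labels Race group per woman.
#' @param thresholds Optional named list of [compute_thresholds()] objects
#'   per variant; computed from the supplied risks and weights when `NULL`.
#' @return Tibble with `variant` (including `"difference"` rows), `race`
#'   (including `"overall"`), `category` and `weighted_pct`.
#' @export
category_prevalence <- function(risks_by_variant, weights = NULL,
                                race_labels, thresholds = NULL) {
  variants <- c("include_race", "exclude_race")
  stopifnot(all(variants %in% names(risks_by_variant)))
  n <- length(risks_by_variant[[1L]])
  if (length(risks_by_variant[[2L]]) != n || length(race_labels) != n) {
    abort("Both variants' risks and race labels must align.",
          class = "screenaudit_contract_error")
  }
  if (is.null(weights)) weights <- rep(1, n)
  zero_races <- setdiff(unique(race_labels),
                        unique(race_labels[weights > 0]))
  if (length(zero_races)) {
    warn(paste("Race group(s) with zero total weight omitted:",
               paste(zero_races, collapse = ", ")))
  }
  tab <- purrr::map_dfr(variants, function(v) {
    thr <- if (is.null(thresholds)) {
      compute_thresholds(risks_by_variant[[v]], weights, variant = v)
    } else {
      thresholds[[v]]
    }
    cat_ <- assign_category(risks_by_variant[[v]], thr)
    base <- tibble::tibble(race = race_labels, category = cat_, w = weights)
    totals <- dplyr::count(base, .data$race, wt = .data$w, name = "wtot")
    per_race <- base |>
      dplyr::count(.data$race, .data$category, wt = .data$w, name = "wsum",
                   .drop = FALSE) |>
      dplyr::left_join(totals, by = "race") |>
      dplyr::mutate(weighted_pct = 100 * .data$wsum / .data$wtot) |>
      dplyr::select("race", "category", "weighted_pct")
    overall <- base |>
      dplyr::count(.data$category, wt = .data$w, name = "wsum",
                   .drop = FALSE) |>
      dplyr::mutate(weighted_pct = 100 * .data$wsum / sum(weights),
                    race = "overall") |>
      dplyr::select("race", "category", "weighted_pct")
    dplyr::bind_rows(per_race, overall) |>
      dplyr::mutate(variant = v,
                    weighted_pct = ifelse(is.nan(.data$weighted_pct), NA_real_,
                                          .data$weighted_pct))
  })
  diff_tab <- tab |>
    tidyr::pivot_wider(names_from = "variant",
                       values_from = "weighted_pct") |>
    dplyr::mutate(variant = "difference",
                  weighted_pct = .data$exclude_race - .data$include_race) |>
    dplyr::select("race", "category", "variant", "weighted_pct")
  dplyr::bind_rows(tab, diff_tab) |>
    dplyr::select("variant", "race", "category", "weighted_pct") |>
    dplyr::arrange(.data$category, .data$race)
}

#' Weighted median and IQR of cumulative risk by race and cancer status
#'
#' Summarizes the cumulative-risk distribution per race group and
#' advanced-cancer status (and optionally per variant and interval), using
#' the package's weighted-percentile rule for the median and the 25th/75th
#' percentiles.
#'
#' @param risks Cumulative risks.
#' @param race_labels Race group per woman.
#' @param cancer_status Logical advanced-cancer indicator per woman.
#' @param weights Optional positive weights.
#' @param variant,interval Optional additional grouping labels.
#' @return Tibble with one row per populated cell: `median`, `q25`, `q75`
#'   and the cell's weighted size; empty cells are absent (reported missing).
#' @export
median_iqr_by_status <- function(risks, race_labels, cancer_status,
                                 weights = NULL, variant = NULL,
                                 interval = NULL) {
  n <- length(risks)
  if (is.null(weights)) weights <- rep(1, n)
  df <- tibble::tibble(
    risk = risks, race = race_labels,
    status = ifelse(cancer_status, "advanced", "no advanced"),
    w = weights,
    variant = variant %||% NA_character_,
    interval = interval %||% NA_character_
  )
  df |>
    dplyr::group_by(.data$variant, .data$interval, .data$race,
                    .data$status) |>
    dplyr::summarise(
      n = dplyr::n(),
      median = weighted_quantile(.data$risk, .data$w, 0.5),
      q25 = weighted_quantile(.data$risk, .data$w, 0.25),
      q75 = weighted_quantile(.data$risk, .data$w, 0.75),
      .groups = "drop"
    )
}

#' Share of women at intermediate or high risk, by race and cancer status
#'
#' @param risks Cumulative risks.
#' @param thresholds The variant's [compute_thresholds()].
#' @param race_labels,cancer_status,weights As in [median_iqr_by_status()].
#' @return Tibble with `race`, `status`, `pct_intermediate_high`.
#' @export
intermediate_high_share <- function(risks, thresholds, race_labels,
                                    cancer_status, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(risks))
  cat_ <- assign_category(risks, thresholds)
  tibble::tibble(
    race = race_labels,
    status = ifelse(cancer_status, "advanced", "no advanced"),
    hi = cat_ %in% c("intermediate", "high"),
    w = weights
  ) |>
    dplyr::group_by(.data$race, .data$status) |>
    dplyr::summarise(
      pct_intermediate_high = 100 * sum(.data$w[.data$hi]) / sum(.data$w),
      .groups = "drop"
    )
}

#' Reclassification deltas between model variants
#'
#' Joins per-cell intermediate/high shares from the two variants (computed on
#' identical women) and reports the change under race exclusion
#' (`exclude - include`): a negative delta means the race-excluded model
#' moves that cell out of the intermediate/high categories.
#'
#' @param summary_include,summary_exclude [intermediate_high_share()] tables
#'   for the include-race and exclude-race variants.
#' @return Tibble with `race`, `status`, shares under both variants and
#'   `delta`.
#' @export
compare_models <- function(summary_include, summary_exclude) {
  need <- c("race", "status", "pct_intermediate_high")
  stopifnot(all(need %in% names(summary_include)),
            all(need %in% names(summary_exclude)))
  joined <- dplyr::full_join(
    dplyr::rename(summary_include, include_race = "pct_intermediate_high"),
    dplyr::rename(summary_exclude, exclude_race = "pct_intermediate_high"),
    by = c("race", "status")
  )
  if (anyNA(joined$include_race) || anyNA(joined$exclude_race)) {
    abort("compare_models(): the two summaries cover different cells.",
          class = "screenaudit_contract_error")
  }
  dplyr::mutate(joined, delta = .data$exclude_race - .data$include_race)
}
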