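#' Expected/observed calibration ratio by group
#'
#' Mean calibration after one screening round: per group, the expected count
#' is the sum of predicted advanced-cancer probabilities and the observed
#' count is the number of advanced cancers in the window; their ratio is 1
#' under perfect mean calibration, above 1 for overestimation and below 1
#' for underestimation. Groups with no observed events are flagged
#' non-estimable rather than returning an infinite ratio.
#'
#' @param predictions Per-exam predicted probabilities in `[0, 1]`.
#' @param outcomes Per-exam outcomes (`"advanced_cancer"` counts as an event).
#' @param group_labels Optional group labels (e.g. race); `NULL` gives a
#'   single overall row.
#' @param variant Optional variant tag carried into the result.
#' @return Tibble with `group`, `n`, `expected`, `observed`, `eo_ratio`,
#'   `estimable`.
#' @export
expected_observed <- function(predictions, outcomes, group_labels = NULL,
                              variant = NA_character_) {
  stopifnot(length(predictions) == length(outcomes))
  if (any(predictions < -1e-12 | predictions > 1 + 1e-12)) {
    abort("Predictions must lie in [0, 1].",
          class = "screenaudit_contract_error")
  }
  if (is.null(group_labels)) group_labels <- rep("overall",
                                                 length(predictions))
  stopifnot(length(group_labels) == length(predictions))
  tibble::tibble(group = group_labels,
                 pred = predictions,
                 event = outcomes == "advanced_cancer") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     expected = sum(.data$pred),
                     observed = sum(.data$event),
                     .groups = "drop") |>
    dplyr::mutate(
      estimable = .data$observed > 0,
      eo_ratio = ifelse(.data$estimable, .data$expected / .data$observed,
                        NA_real_),
      variant = variant
    )
}

#' Bootstrap confidence intervals for expected/observed ratios
#'
#' Resamples women (with all their exams) with replacement, recomputes each
#' group's E/O per replicate, and reports percentile 2.5/97.5 limits.
#' Replicates in which a group has no observed events are dropped for that
#' group and counted; a group with more than 10\% dropped replicates carries
#' a warning flag.
#'
#' @param woman_id Per-exam woman identifiers (the resampling unit).
#' @param predictions,outcomes,group_labels As in [expected_observed()].
#' @param b Number of bootstrap replicates (default 1000).
#' @param seed Integer seed (replicates are seed-deterministic).
#' @return Tibble with `group`, `eo_low`, `eo_high`, `b_used`, `b_dropped`,
#'   `unstable`.
#' @export
bootstrap_eo_ci <- function(woman_id, predictions, outcomes,
                            group_labels = NULL, b = 1000, seed = 1) {
  b <- as_count(b, "b")
  if (is.null(group_labels)) group_labels <- rep("overall",
                                                 length(predictions))
  stopifnot(length(woman_id) == length(predictions),
            length(outcomes) == length(predictions),
            length(group_labels) == length(predictions))
  women <- unique(woman_id)
  wi <- match(woman_id, women)
  groups <- sort(unique(group_labels))
  gi <- match(group_labels, groups)
  nw <- length(women)
  ng <- length(groups)
  # Per-woman, per-group sufficient statistics: a resample only needs how
  # many times each woman is drawn.
  Ewg <- matrix(0, nw, ng)
  Owg <- matrix(0, nw, ng)
  ev <- as.numeric(outcomes == "advanced_cancer")
  for (g in seq_len(ng)) {
    sel <- gi == g
    Ewg[, g] <- rowsum_vec(predictions[sel], wi[sel], nw)
    Owg[, g] <- rowsum_vec(ev[sel], wi[sel], nw)
  }
  ratios <- matrix(NA_real_, b, ng)
  with_seed(derive_seed(seed, "eo-bootstrap"), {
    for (r in seq_len(b)) {
      counts <- tabulate(sample.int(nw, nw, replace = TRUE), nbins = nw)
      E <- drop(crossprod(Ewg, counts))
      O <- drop(crossprod(Owg, counts))
      ratios[r, ] <- ifelse(O > 0, E / O, NA_real_)
    }
  })
  purrr::map_dfr(seq_len(ng), function(g) {
    reps <- ratios[, g]
    dropped <- sum(is.na(reps))
    reps <- reps[!is.na(reps)]
    tibble::tibble(
      group = groups[g],
      eo_low = if (length(reps)) unname(quantile(reps, 0.025, type = 1))
               else NA_real_,
      eo_high = if (length(reps)) unname(quantile(reps, 0.975, type = 1))
                else NA_real_,
      b_used = length(reps),
      b_dropped = dropped,
      unstable = dropped > 0.1 * b
    )
  })
}

rowsum_vec <- function(x, index, n) {
  out <- numeric(n)
  agg <- rowsum(x, index)
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Mann-Whitney area under the ROC curve
#'
#' Probability that a randomly chosen case receives a higher prediction than
#' a randomly chosen non-case, with ties contributing 1/2 (midrank form).
#'
#' @param predictions Numeric scores.
#' @param is_event Logical (or 0/1) event indicator.
#' @return AUC in `[0, 1]`, or `NA` when either class is empty.
#' @export
auc_mann_whitney <- function(predictions, is_event) {
  is_event <- as.logical(is_event)
  n1 <- sum(is_event)
  n0 <- sum(!is_event)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(predictions)
  (sum(r[is_event]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUC for the per-round advanced-cancer model
#'
#' Folds partition women (not exams), with fold assignment stratified on
#' whether a woman has an advanced cancer so every fold contains events. For
#' each fold, models are fit on the remaining folds (once per imputation)
#' and pooled predictions are issued for the held-out exams; a single AUC is
#' then computed over all out-of-fold predictions (Mann-Whitney form),
#' overall and within each group. Confidence intervals come from a
#' woman-level bootstrap of the out-of-fold predictions.
#'
#' @param data An `imputed_cohort` or complete records data frame.
#' @param spec A [model_spec()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed for fold assignment and bootstrap.
#' @param group_labels Optional per-exam group labels; exams with `NA` group
#'   contribute to the overall AUC only.
#' @param b_ci Bootstrap replicates for the CI (default 200; 0 skips CIs).
#' @return Tibble with `group`, `auc`, `auc_low`, `auc_high`, `folds`, `n`,
#'   `events`, `estimable`, plus (as an attribute `"oof"`) the out-of-fold
#'   predictions.
#' @export
cross_validated_auc <- function(data, spec = model_spec(), k = 5, seed = 1,
                                group_labels = NULL, b_ci = 200) {
  k <- as_count(k, "k")
  if (k < 2L) abort("k must be at least 2.",
                    class = "screenaudit_contract_error")
  records <- if (inherits(data, "imputed_cohort")) {
    data$completions[[1L]]
  } else {
    tibble::as_tibble(data)
  }
  n <- nrow(records)
  women <- unique(records$woman_id)
  case_woman <- records |>
    dplyr::group_by(.data$woman_id) |>
    dplyr::summarise(case = any(.data$outcome == "advanced_cancer"),
                     .groups = "drop")
  fold_of <- integer(length(women))
  names(fold_of) <- case_woman$woman_id
  with_seed(derive_seed(seed, "cv-folds"), {
    # Shuffle within case status, then deal fold labels round-robin over the
    # concatenated order: events spread as evenly as possible across folds.
    ordered <- c(sample(case_woman$woman_id[case_woman$case]),
                 sample(case_woman$woman_id[!case_woman$case]))
    fold_of[ordered] <- rep_len(seq_len(k), length(ordered))
  })
  exam_fold <- unname(fold_of[records$woman_id])
  oof <- numeric(n)
  for (f in seq_len(k)) {
    test_idx <- which(exam_fold == f)
    train_idx <- which(exam_fold != f)
    if (inherits(data, "imputed_cohort")) {
      preds <- vapply(data$completions, function(comp) {
        fit <- fit_round_models(comp[train_idx, , drop = FALSE], spec)
        predict_round_risk(fit, comp[test_idx, , drop = FALSE], "advanced")
      }, numeric(length(test_idx)))
      oof[test_idx] <- pool_predictions(matrix(preds,
                                               nrow = length(test_idx)))
    } else {
      fit <- fit_round_models(records[train_idx, , drop = FALSE], spec)
      oof[test_idx] <- predict_round_risk(fit,
                                          records[test_idx, , drop = FALSE],
                                          "advanced")
    }
  }
  is_event <- records$outcome == "advanced_cancer"
  grp <- group_labels %||% rep(NA_character_, n)
  levels_out <- c("overall", sort(unique(grp[!is.na(grp)])))
  res <- purrr::map_dfr(levels_out, function(g) {
    sel <- if (g == "overall") rep(TRUE, n) else !is.na(grp) & grp == g
    a <- auc_mann_whitney(oof[sel], is_event[sel])
    ci <- c(NA_real_, NA_real_)
    if (b_ci > 0 && !is.na(a)) {
      ci <- bootstrap_auc_ci(records$woman_id[sel], oof[sel], is_event[sel],
                             b = b_ci, seed = seed)
    }
    tibble::tibble(group = g, auc = a, auc_low = ci[1L], auc_high = ci[2L],
                   folds = k, n = sum(sel), events = sum(is_event[sel]),
                   estimable = !is.na(a))
  })
  attr(res, "oof") <- oof
  res
}

bootstrap_auc_ci <- function(woman_id, predictions, is_event, b = 200,
                             seed = 1) {
  women <- unique(woman_id)
  by_woman <- split(seq_along(woman_id), match(woman_id, women))
  reps <- numeric(b)
  with_seed(derive_seed(seed, "auc-bootstrap"), {
    for (r in seq_len(b)) {
      draw <- sample.int(length(women), replace = TRUE)
      idx <- unlist(by_woman[draw], use.names = FALSE)
      reps[r] <- auc_mann_whitney(predictions[idx], is_event[idx])
    }
  })
  reps <- reps[!is.na(reps)]
  if (!length(reps)) return(c(NA_real_, NA_real_))
  unname(quantile(reps, c(0.025, 0.975), type = 1))
}
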