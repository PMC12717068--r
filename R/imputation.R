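#' Multiple imputation by chained equations for screening-exam covariates
#'
#' Produces `m` completed copies of the cohort. Each maskable covariate with
#' missing values gets a conditional model given all other covariates, age,
#' screening interval and the observed outcome: binary variables (menopause,
#' family history) use logistic regression, multi-level variables (race,
#' biopsy history, density, BMI) use multinomial logistic regression. Missing
#' entries are initialized by draws from the observed marginal distribution,
#' then updated over `iterations` chained sweeps in ascending order of
#' missingness rate; each completion uses an independent seed derived from
#' the master seed. Unknown menopausal status is imputed to pre or post only.
#'
#' A conditional fit that runs into separation (fitted probabilities pinned at
#' 0 or 1) falls back to a penalized fit — Firth-type for binary models, a
#' small weight-decay penalty for multinomial models — and the fallback is
#' recorded in the result's `notes`.
#'
#' @param records Exam records, possibly with `NA` in maskable covariates;
#'   `outcome`, `interval` and `age` must be complete.
#' @param m Number of imputations (default 15).
#' @param seed Master seed.
#' @param iterations Chained-equation sweeps per completion (default 10).
#' @return An object of class `imputed_cohort`: list with `completions`
#'   (list of `m` complete tibbles), `m`, `seed`, `iteration_count`, `notes`.
#' @export
fit_mice <- function(records, m = 15, seed = 1, iterations = 10) {
  m <- as_count(m, "m")
  iterations <- as_count(iterations, "iterations")
  vars <- maskable_variables()
  if (anyNA(records[c("age", "interval", "outcome")])) {
    abort("age, interval and outcome must be complete before imputation.",
          class = "screenaudit_imputation_error")
  }
  miss_rate <- vapply(vars, function(v) mean(is.na(records[[v]])), numeric(1))
  if (any(miss_rate == 1)) {
    abort(sprintf("Variable(s) 100%% missing, no conditional model estimable: %s",
                  paste(vars[miss_rate == 1], collapse = ", ")),
          class = "screenaudit_imputation_error")
  }
  to_impute <- vars[miss_rate > 0]
  notes <- character(0)
  if (length(to_impute) == 0L) {
    completions <- rep(list(tibble::as_tibble(records)), m)
    return(structure(list(completions = completions, m = m,
                          seed = as.integer(seed),
                          iteration_count = iterations, notes = notes),
                     class = "imputed_cohort"))
  }
  # Visit order: ascending missingness rate.
  to_impute <- to_impute[order(miss_rate[to_impute])]
  lv <- covariate_level_list()
  miss_idx <- lapply(to_impute, function(v) which(is.na(records[[v]])))
  names(miss_idx) <- to_impute

  completions <- vector("list", m)
  for (imp in seq_len(m)) {
    comp <- tibble::as_tibble(records)
    with_seed(derive_seed(seed, paste0("mice-", imp)), {
      # Initial fill: draw from the observed marginal distribution.
      for (v in to_impute) {
        obs <- comp[[v]][!is.na(comp[[v]])]
        comp[[v]][miss_idx[[v]]] <- sample(obs, length(miss_idx[[v]]),
                                           replace = TRUE)
      }
      for (it in seq_len(iterations)) {
        for (v in to_impute) {
          drawn <- draw_conditional(comp, v, miss_idx[[v]], lv[[v]])
          comp[[v]][miss_idx[[v]]] <- drawn$values
          if (length(drawn$note)) {
            notes <- unique(c(notes, sprintf("imp %d sweep %d: %s",
                                             imp, it, drawn$note)))
          }
        }
      }
    })
    completions[[imp]] <- comp
  }
  structure(list(completions = completions, m = m, seed = as.integer(seed),
                 iteration_count = iterations, notes = notes),
            class = "imputed_cohort")
}

# Fit the conditional model for `target` on current completed data and draw
# replacement values for its originally missing rows.
draw_conditional <- function(comp, target, idx, target_levels) {
  predictors <- c("age", "interval", "outcome",
                  setdiff(maskable_variables(), target))
  df <- comp[predictors]
  df$interval <- factor(df$interval, levels = interval_levels())
  df$outcome <- factor(df$outcome, levels = outcome_levels())
  for (v in setdiff(maskable_variables(), target)) {
    df[[v]] <- factor(df[[v]])
  }
  present <- target_levels[target_levels %in% comp[[target]][-idx]]
  y <- factor(comp[[target]], levels = present)
  note <- character(0)
  if (length(present) < 2L) {
    # Degenerate conditional: only one observed level.
    return(list(values = rep(present, length(idx)), note = note))
  }
  train <- which(!seq_len(nrow(comp)) %in% idx)
  X <- stats::model.matrix(~ ., data = df)
  keep <- which(apply(X[train, , drop = FALSE], 2L, function(z) {
    stats::var(z) > 0
  }))
  keep <- union(1L, keep)
  X <- X[, keep, drop = FALSE]
  if (length(present) == 2L) {
    yb <- as.integer(y[train]) - 1L
    fit <- suppressWarnings(glm.fit(X[train, , drop = FALSE], yb,
                                    family = binomial()))
    beta <- fit$coefficients
    p_train <- fit$fitted.values
    if (any(!is.finite(beta)) || any(p_train < 1e-10) ||
        any(p_train > 1 - 1e-10)) {
      beta <- firth_logistic(X[train, , drop = FALSE], yb)$coefficients
      note <- sprintf("penalized fallback for conditional model of '%s'",
                      target)
    }
    p <- inv_logit(drop(X[idx, , drop = FALSE] %*% beta))
    vals <- present[1L + rbinom(length(idx), 1L, p)]
  } else {
    dat <- data.frame(.y = y, df)
    fit <- try(nnet::multinom(.y ~ ., data = dat[train, ], trace = FALSE,
                              maxit = 200, MaxNWts = 5000), silent = TRUE)
    pr <- if (!inherits(fit, "try-error")) {
      predict(fit, newdata = dat[idx, , drop = FALSE], type = "probs")
    }
    if (inherits(fit, "try-error") || anyNA(pr)) {
      fit <- nnet::multinom(.y ~ ., data = dat[train, ], trace = FALSE,
                            maxit = 200, MaxNWts = 5000, decay = 0.01)
      pr <- predict(fit, newdata = dat[idx, , drop = FALSE], type = "probs")
      note <- sprintf("penalized fallback for conditional model of '%s'",
                      target)
    }
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = length(idx))
    vals <- sample_levels(pr, present)
  }
  list(values = vals, note = note)
}

#' Pool per-imputation risk predictions by averaging
#'
#' Risk predictions from the `m` completed datasets are pooled on the
#' probability scale by their arithmetic mean, exam by exam.
#'
#' @param per_imputation A numeric matrix (exams by imputations) or a list of
#'   equal-length probability vectors.
#' @return Numeric vector of pooled probabilities.
#' @export
pool_predictions <- function(per_imputation) {
  if (is.list(per_imputation) && !is.data.frame(per_imputation)) {
    lens <- lengths(per_imputation)
    if (length(unique(lens)) != 1L) {
      abort("All per-imputation prediction vectors must have equal length.",
            class = "screenaudit_contract_error")
    }
    per_imputation <- do.call(cbind, per_imputation)
  }
  per_imputation <- as.matrix(per_imputation)
  if (any(per_imputation < -1e-12 | per_imputation > 1 + 1e-12,
          na.rm = TRUE)) {
    abort("Predictions must lie in [0, 1].",
          class = "screenaudit_contract_error")
  }
  rowMeans(per_imputation)
}

#' @export
print.imputed_cohort <- function(x, ...) {
  cat(sprintf("<imputed_cohort> m = %d completions of %d records (%d sweeps)\n",
              x$m, nrow(x$completions[[1L]]), x$iteration_count))
  if (length(x$notes)) cat(" notes:", length(x$notes), "penalized fallbacks\n")
  invisible(x)
}
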