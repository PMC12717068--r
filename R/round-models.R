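#' Specify the per-round risk model
#'
#' Fixed covariate specification for the per-screening-round logistic models:
#' age (linear and quadratic), race and ethnicity (optional), first-degree
#' family history, benign biopsy history, BMI category and BI-RADS density,
#' fit separately within each of the four menopause-by-interval strata. The
#' race-excluded variant differs from the race-included variant only by the
#' removal of the race indicator block.
#'
#' @param include_race Include race and ethnicity indicators?
#' @param reference_levels Named list giving the reference level of each
#'   categorical covariate.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(include_race = TRUE,
                       reference_levels = list(
                         race_ethnicity = "White",
                         family_history = "no",
                         biopsy_history = "none",
                         density = "fatty",
                         bmi = "normal"
                       )) {
  lv <- covariate_level_list()
  for (v in names(reference_levels)) {
    if (!reference_levels[[v]] %in% lv[[v]]) {
      abort(sprintf("Reference level '%s' is not a level of '%s'.",
                    reference_levels[[v]], v),
            class = "screenaudit_config_error")
    }
  }
  covs <- c(if (include_race) "race_ethnicity", "family_history",
            "biopsy_history", "bmi", "density")
  structure(
    list(include_race = isTRUE(include_race),
         variant = if (include_race) "include_race" else "exclude_race",
         strata = stratum_labels(),
         categorical_covariates = covs,
         reference_levels = reference_levels),
    class = "model_spec"
  )
}

#' Encode screening-exam records as a model design matrix
#'
#' Builds the design row for each record: an intercept, raw age and age
#' squared, and one 0/1 indicator per non-reference level of each categorical
#' covariate in the specification (race indicators present only when the
#' specification includes race).
#'
#' @param records Fully observed exam records (post-imputation).
#' @param spec A [model_spec()].
#' @return Numeric matrix with named columns; indicator columns are named
#'   `"variable=level"`.
#' @export
encode_covariates <- function(records, spec) {
  stopifnot(inherits(spec, "model_spec"))
  lv <- covariate_level_list()
  n <- nrow(records)
  cols <- list("(Intercept)" = rep(1, n),
               age = records$age,
               age_sq = records$age^2)
  for (v in spec$categorical_covariates) {
    vals <- records[[v]]
    if (anyNA(vals) || !all(vals %in% lv[[v]])) {
      bad <- unique(vals[is.na(vals) | !vals %in% lv[[v]]])
      abort(sprintf("Unexpected level(s) in '%s': %s", v,
                    paste(ifelse(is.na(bad), "NA", bad), collapse = ", ")),
            class = "screenaudit_encoding_error")
    }
    for (level in setdiff(lv[[v]], spec$reference_levels[[v]])) {
      cols[[paste0(v, "=", level)]] <- as.numeric(vals == level)
    }
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(cols)
  mat
}

# Age scaling used only inside fitting for numerical conditioning of the raw
# quadratic; coefficients are mapped back to the raw age / age^2 basis.
age_scale_center <- 57
age_scale_width <- 10

scale_design <- function(X) {
  s <- (X[, "age"] - age_scale_center) / age_scale_width
  X[, "age"] <- s
  X[, "age_sq"] <- s^2
  X
}

# Linear map raw <- M %*% scaled over the full coefficient vector.
unscale_map <- function(terms) {
  k <- length(terms)
  M <- diag(k)
  dimnames(M) <- list(terms, terms)
  cc <- age_scale_center
  d <- age_scale_width
  M["(Intercept)", "age"] <- -cc / d
  M["(Intercept)", "age_sq"] <- cc^2 / d^2
  M["age", "age"] <- 1 / d
  M["age", "age_sq"] <- -2 * cc / d^2
  M["age_sq", "age_sq"] <- 1 / d^2
  M
}

# Maximum-likelihood logistic fit with an explicit score-convergence check
# and Firth-penalized fallback under separation. Covariate levels absent
# from the stratum (constant columns) are dropped from the fit and reported
# as zero coefficients with NA standard errors.
fit_logistic <- function(X, y, label) {
  full_terms <- colnames(X)
  keep <- vapply(seq_len(ncol(X)), function(j) {
    j == 1L || stats::var(X[, j]) > 0
  }, logical(1))
  # Aliased (collinear) columns are dropped the way glm drops them.
  qrx <- qr(X[, keep, drop = FALSE])
  if (qrx$rank < sum(keep)) {
    keep[which(keep)[-qrx$pivot[seq_len(qrx$rank)]]] <- FALSE
  }
  X <- X[, keep, drop = FALSE]
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  )
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  penalized <- FALSE
  p <- inv_logit(drop(X %*% beta))
  score <- drop(crossprod(X, y - p))
  # A couple of Newton polish steps to push the score norm to tolerance.
  for (i in 1:5) {
    if (!all(is.finite(score)) || max(abs(score)) < 1e-8) break
    W <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X * sqrt(W))
    step <- try(solve(H, score), silent = TRUE)
    if (inherits(step, "try-error")) break
    beta <- beta + step
    p <- inv_logit(drop(X %*% beta))
    score <- drop(crossprod(X, y - p))
  }
  if (any(!is.finite(beta)) || any(!is.finite(score)) ||
      max(abs(beta)) > 25 || max(abs(score)) > 1e-6) {
    ff <- firth_logistic(X, y)
    beta <- ff$coefficients
    V <- ff$vcov
    penalized <- TRUE
  } else {
    W <- pmax(p * (1 - p), 1e-12)
    V <- solve(crossprod(X * sqrt(W)))
  }
  beta_full <- setNames(numeric(length(full_terms)), full_terms)
  beta_full[keep] <- beta
  V_full <- matrix(NA_real_, length(full_terms), length(full_terms),
                   dimnames = list(full_terms, full_terms))
  V_full[keep, keep] <- V
  list(coefficients = beta_full, vcov = V_full, penalized = penalized,
       converged = penalized || max(abs(score)) < 1e-8, label = label,
       dropped = full_terms[!keep])
}

#' Firth-penalized logistic regression
#'
#' Newton iteration on the Jeffreys-prior penalized score
#' `U*(b) = X'(y - p + h (1/2 - p))` with `h` the leverage diagonal; used as
#' the separation guard behind the maximum-likelihood fits.
#'
#' @param X Design matrix with intercept column.
#' @param y 0/1 response.
#' @param max_iter,tol Iteration controls.
#' @return List with `coefficients` and `se`.
#' @export
firth_logistic <- function(X, y, max_iter = 50, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  I_inv <- NULL
  for (i in seq_len(max_iter)) {
    p <- inv_logit(drop(X %*% beta))
    W <- pmax(p * (1 - p), 1e-12)
    I_mat <- crossprod(X * sqrt(W))
    I_inv <- solve(I_mat)
    h <- rowSums((X %*% I_inv) * X) * W
    U <- drop(crossprod(X, y - p + h * (0.5 - p)))
    if (max(abs(U)) < tol) break
    step <- drop(I_inv %*% U)
    # Step halving for stability.
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    beta <- beta + step
  }
  list(coefficients = setNames(drop(beta), colnames(X)),
       se = setNames(sqrt(diag(I_inv)), colnames(X)),
       vcov = I_inv)
}

#' Fit per-round logistic models for advanced cancer and competing events
#'
#' Within each menopause-by-interval stratum, fits (1) a logistic model for
#' advanced cancer on all exams and (2) a logistic model for competing events
#' on the exams without advanced cancer (the tree factorization of the
#' three-state outcome). With an [fit_mice()] result as input, the models are
#' fit once per completed dataset; a plain complete data frame is treated as
#' a single completion.
#'
#' @param data An `imputed_cohort` or a complete records data frame.
#' @param spec A [model_spec()].
#' @return Object of class `round_model_fit` holding, per imputation and
#'   stratum, raw-scale coefficients and standard errors for both event
#'   models plus convergence diagnostics.
#' @export
fit_round_models <- function(data, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  completions <- if (inherits(data, "imputed_cohort")) {
    data$completions
  } else {
    list(tibble::as_tibble(data))
  }
  fits <- lapply(completions, function(comp) fit_one_completion(comp, spec))
  structure(
    list(variant = spec$variant, spec = spec, fits = fits,
         m = length(fits)),
    class = "round_model_fit"
  )
}

fit_one_completion <- function(records, spec) {
  X <- scale_design(encode_covariates(records, spec))
  terms <- colnames(X)
  M <- unscale_map(terms)
  strata <- stratum_of(records$menopause, records$interval)
  out <- list()
  for (s in stratum_labels()) {
    idx <- which(strata == s)
    if (!length(idx)) {
      abort(sprintf("Stratum '%s' is empty.", s),
            class = "screenaudit_fitting_error")
    }
    y_adv <- as.numeric(records$outcome[idx] == "advanced_cancer")
    if (sum(y_adv) == 0 || sum(y_adv) == length(y_adv)) {
      abort(sprintf("Stratum '%s' has %s advanced-cancer events; cannot fit.",
                    s, if (sum(y_adv) == 0) "no" else "only"),
            class = "screenaudit_fitting_error")
    }
    adv <- fit_logistic(X[idx, , drop = FALSE], y_adv, paste0(s, "/advanced"))
    sub <- idx[records$outcome[idx] != "advanced_cancer"]
    y_cmp <- as.numeric(records$outcome[sub] == "competing_event")
    if (sum(y_cmp) == 0 || sum(y_cmp) == length(y_cmp)) {
      abort(sprintf("Stratum '%s' has %s competing events; cannot fit.",
                    s, if (sum(y_cmp) == 0) "no" else "only"),
            class = "screenaudit_fitting_error")
    }
    cmp <- fit_logistic(X[sub, , drop = FALSE], y_cmp, paste0(s, "/competing"))
    unscale <- function(f) {
      raw <- drop(M %*% f$coefficients)
      V_raw <- M %*% f$vcov %*% t(M)
      list(coefficients = setNames(raw, terms),
           se = setNames(sqrt(diag(V_raw)), terms),
           penalized = f$penalized, converged = f$converged)
    }
    out[[s]] <- list(
      advanced = c(unscale(adv), list(n = length(idx), events = sum(y_adv))),
      competing = c(unscale(cmp), list(n = length(sub), events = sum(y_cmp)))
    )
  }
  out
}

#' Predict per-round event probabilities
#'
#' Computes the inverse logit of the fitted linear predictor for each record,
#' using the coefficients of the record's menopause-by-interval stratum. For
#' multiply imputed fits, per-imputation predictions are pooled by averaging
#' on the probability scale (`pool = TRUE`) or returned as an
#' exams-by-imputations matrix.
#'
#' @param fit A [fit_round_models()] result.
#' @param records Fully observed records to predict for.
#' @param event `"advanced"` or `"competing"`.
#' @param pool Average over imputations?
#' @return Numeric vector (pooled) or matrix of probabilities in (0, 1).
#' @export
predict_round_risk <- function(fit, records, event = c("advanced",
                                                       "competing"),
                               pool = TRUE) {
  stopifnot(inherits(fit, "round_model_fit"))
  event <- match.arg(event)
  X <- encode_covariates(records, fit$spec)
  strata <- stratum_of(records$menopause, records$interval)
  bad <- setdiff(unique(strata), stratum_labels())
  if (length(bad)) {
    abort(sprintf("Record stratum not covered by the model: %s",
                  paste(bad, collapse = ", ")),
          class = "screenaudit_prediction_error")
  }
  preds <- vapply(fit$fits, function(one) {
    eta <- numeric(nrow(records))
    for (s in unique(strata)) {
      idx <- which(strata == s)
      beta <- one[[s]][[event]]$coefficients
      eta[idx] <- drop(X[idx, names(beta), drop = FALSE] %*% beta)
    }
    inv_logit(eta)
  }, numeric(nrow(records)))
  preds <- matrix(preds, nrow = nrow(records))
  if (pool) pool_predictions(preds) else preds
}

#' Serialize fitted round models to JSON
#'
#' Writes variant, stratum, event, term, coefficient and standard error for
#' every fitted model (per imputation) to a JSON file.
#'
#' @param fit A [fit_round_models()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
serialize_models <- function(fit, path) {
  jsonlite::write_json(tidy(fit), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @describeIn fit_round_models Tidy per-term coefficient table (one row per
#'   imputation, stratum, event and term).
#' @param x A `round_model_fit`.
#' @param ... Unused.
#' @method tidy round_model_fit
#' @export
tidy.round_model_fit <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(one, imp) {
    purrr::imap_dfr(one, function(st, s) {
      purrr::imap_dfr(st, function(f, ev) {
        tibble::tibble(imputation = imp, stratum = s, event = ev,
                       term = names(f$coefficients),
                       estimate = unname(f$coefficients),
                       std.error = unname(f$se),
                       penalized = f$penalized)
      })
    })
  })
}

#' @describeIn fit_round_models One-row fit summary.
#' @method glance round_model_fit
#' @export
glance.round_model_fit <- function(x, ...) {
  td <- tidy(x)
  first <- x$fits[[1L]]
  tibble::tibble(
    variant = x$variant,
    m = x$m,
    strata = length(first),
    n = sum(vapply(first, function(s) s$advanced$n, numeric(1))),
    events_advanced = sum(vapply(first, function(s) s$advanced$events,
                                 numeric(1))),
    events_competing = sum(vapply(first, function(s) s$competing$events,
                                  numeric(1))),
    penalized_fits = sum(td$penalized[!duplicated(
      td[c("imputation", "stratum", "event")])])
  )
}

#' @export
print.round_model_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<round_model_fit> variant = %s, m = %d, %d strata, %d exams, %d advanced events\n",
    g$variant, g$m, g$strata, g$n, g$events_advanced))
  invisible(x)
}
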