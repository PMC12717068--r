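#' Configure an end-to-end model-bias audit run
#'
#' Bundles the generator configuration with the analysis constants: 15
#' imputations, 5 cross-validation folds, 1000 bootstrap replicates and the
#' 6-year risk horizon by default.
#'
#' @param generator A [generator_config()].
#' @param m_imputations Imputations for [fit_mice()] (default 15).
#' @param mice_iterations Chained-equation sweeps (default 10).
#' @param cv_folds Cross-validation folds (default 5).
#' @param bootstrap_b Bootstrap replicates for E/O intervals (default 1000).
#' @param auc_bootstrap_b Bootstrap replicates for AUC intervals
#'   (default 200).
#' @param seed Master seed fanned out to stage-specific seeds.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            m_imputations = 15, mice_iterations = 10,
                            cv_folds = 5, bootstrap_b = 1000,
                            auc_bootstrap_b = 200, seed = 1) {
  stopifnot(inherits(generator, "generator_config"))
  structure(
    list(generator = generator,
         m_imputations = as_count(m_imputations, "m_imputations"),
         mice_iterations = as_count(mice_iterations, "mice_iterations"),
         cv_folds = as_count(cv_folds, "cv_folds"),
         bootstrap_b = as_count(bootstrap_b, "bootstrap_b"),
         auc_bootstrap_b = as.integer(auc_bootstrap_b),
         horizon_years = 6L,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Missing keys take their defaults; unknown keys are rejected with an error
#' naming them. The `generator` block mirrors [generator_config()] argument
#' names.
#'
#' @param path Path to a YAML (or JSON) configuration file.
#' @return A validated [pipeline_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "screenaudit_config_error")
  }
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  top_keys <- c("generator", "m_imputations", "mice_iterations", "cv_folds",
                "bootstrap_b", "auc_bootstrap_b", "seed")
  unknown <- setdiff(names(raw), top_keys)
  if (length(unknown)) {
    abort(paste("Unknown configuration keys:",
                paste(unknown, collapse = ", ")),
          class = "screenaudit_config_error")
  }
  gen_raw <- raw$generator %||% list()
  gen_keys <- names(formals(generator_config))
  unknown_gen <- setdiff(names(gen_raw), gen_keys)
  if (length(unknown_gen)) {
    abort(paste("Unknown generator keys:",
                paste(unknown_gen, collapse = ", ")),
          class = "screenaudit_config_error")
  }
  to_named <- function(x) if (is.list(x)) unlist(x) else x
  for (k in c("interval_probs", "race_probs", "missingness_rates", "mar")) {
    if (!is.null(gen_raw[[k]])) gen_raw[[k]] <- to_named(gen_raw[[k]])
  }
  gen <- do.call(generator_config, gen_raw)
  args <- raw[setdiff(names(raw), "generator")]
  do.call(pipeline_config, c(list(generator = gen), args))
}

#' Run the full race-aware vs race-free model audit
#'
#' Orchestrates generate, mask, impute, fit both model variants, evaluate
#' calibration and discrimination, compound cumulative risks, stratify into
#' percentile categories and compare the variants. All randomness derives
#' from the configuration's master seed, so identical configurations give
#' identical results.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, [write_reports()]
#'   is called on the results.
#' @return An object of class `audit_report`: a list of result tibbles
#'   (`characteristics`, `calibration`, `discrimination`,
#'   `cumulative_risks`, `thresholds`, `category_prevalence`,
#'   `risk_summaries`, `reclassification`), the fitted models, the cohort
#'   and a manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "screenaudit_pipeline_error")
    })
  }
  gen <- config$generator

  sim <- stage("generate", simulate_cohort(gen))
  records <- sim$records
  say("generate: %d exams, %d advanced, %d competing", nrow(records),
      sum(records$outcome == "advanced_cancer"),
      sum(records$outcome == "competing_event"))

  characteristics <- stage("characterize", summarize_characteristics(records))

  imputed <- stage("impute", fit_mice(records, m = config$m_imputations,
                                      seed = config$seed,
                                      iterations = config$mice_iterations))
  say("impute: m = %d completions", imputed$m)

  specs <- list(include_race = model_spec(TRUE),
                exclude_race = model_spec(FALSE))
  fits <- stage("fit", lapply(specs, function(sp) {
    fit_round_models(imputed, sp)
  }))
  say("fit: both variants over %d strata", length(stratum_labels()))

  # Covariates for evaluation/grouping come from the first completion; race
  # observed in the data is used where available.
  comp1 <- imputed$completions[[1L]]
  race_grp <- records$race_ethnicity

  calibration <- stage("calibrate", purrr::map_dfr(
    names(fits), function(v) {
      purrr::map_dfr(interval_levels(), function(iv) {
        sel <- comp1$interval == iv
        preds <- predict_round_risk(fits[[v]], comp1[sel, , drop = FALSE],
                                    "advanced")
        eo <- expected_observed(preds, records$outcome[sel], race_grp[sel],
                                variant = v)
        ci <- bootstrap_eo_ci(records$woman_id[sel], preds,
                              records$outcome[sel], race_grp[sel],
                              b = config$bootstrap_b, seed = config$seed)
        dplyr::left_join(eo, ci, by = "group") |>
          dplyr::mutate(interval = iv)
      })
    }))

  discrimination <- stage("discriminate", purrr::map_dfr(
    names(fits), function(v) {
      cross_validated_auc(imputed, specs[[v]], k = config$cv_folds,
                          seed = config$seed, group_labels = race_grp,
                          b_ci = config$auc_bootstrap_b) |>
        dplyr::mutate(variant = v)
    }))

  baseline <- which(comp1$round_index == 1L)
  cumulative_risks <- stage("cumulate", purrr::map_dfr(
    names(fits), function(v) {
      risks <- purrr::map(seq_len(imputed$m), function(c_idx) {
        prof <- imputed$completions[[c_idx]][baseline, , drop = FALSE]
        one_fit <- fits[[v]]
        one_fit$fits <- one_fit$fits[c_idx]
        one_fit$m <- 1L
        cumulative_risk(prof, one_fit)$risk
      })
      risk <- pool_predictions(risks)
      tibble::tibble(
        woman_id = comp1$woman_id[baseline],
        interval = comp1$interval[baseline],
        variant = v,
        risk = risk,
        risk_pct = round_half_up(100 * risk, 3)
      )
    }))
  # Advanced-cancer status per woman (any exam) at her baseline row.
  adv_women <- unique(records$woman_id[records$outcome == "advanced_cancer"])
  cumulative_risks$advanced <- cumulative_risks$woman_id %in% adv_women

  reference <- stage("standardize",
                     make_reference_population(comp1[baseline, ]))
  wtab <- compute_weights(comp1[baseline, ], reference)
  say("standardize: cohort-referenced weights (all 1 by construction)")

  base_race <- comp1$race_ethnicity[baseline]
  base_interval <- comp1$interval[baseline]
  thresholds <- stage("stratify", {
    lapply(split_risks(cumulative_risks), function(rv) {
      compute_thresholds(rv$risk_pct, wtab$weight,
                         variant = rv$variant[1L])
    })
  })
  rv <- split_risks(cumulative_risks)
  prevalence <- category_prevalence(
    list(include_race = rv$include_race$risk_pct,
         exclude_race = rv$exclude_race$risk_pct),
    weights = wtab$weight, race_labels = base_race,
    thresholds = thresholds
  )
  risk_summaries <- purrr::map_dfr(names(rv), function(v) {
    median_iqr_by_status(rv[[v]]$risk_pct, base_race, rv[[v]]$advanced,
                         weights = wtab$weight, variant = v,
                         interval = base_interval)
  })
  shares <- lapply(names(rv), function(v) {
    intermediate_high_share(rv[[v]]$risk_pct, thresholds[[v]], base_race,
                            rv[[v]]$advanced, weights = wtab$weight)
  })
  reclassification <- compare_models(shares[[1L]], shares[[2L]])

  manifest <- list(
    seed = config$seed,
    n_women = gen$n_women,
    m_imputations = config$m_imputations,
    cv_folds = config$cv_folds,
    bootstrap_b = config$bootstrap_b,
    config_hash = rlang::hash(config),
    package_version = as.character(utils::packageVersion("screenaudit")),
    complete = TRUE
  )

  report <- structure(
    list(characteristics = characteristics,
         calibration = calibration,
         discrimination = discrimination,
         cumulative_risks = cumulative_risks,
         thresholds = thresholds,
         category_prevalence = prevalence,
         risk_summaries = risk_summaries,
         reclassification = reclassification,
         fits = fits, cohort = records, weights = wtab,
         manifest = manifest, log = log_lines, config = config),
    class = "audit_report"
  )
  if (!is.null(out_dir)) {
    report$paths <- write_reports(report, out_dir)
  }
  report
}

split_risks <- function(cumulative_risks) {
  split(cumulative_risks, cumulative_risks$variant)[c("include_race",
                                                      "exclude_race")]
}

#' Write an audit report bundle to disk
#'
#' Emits the cohort CSV, characteristics / calibration / discrimination /
#' category-prevalence / risk-summary tables as CSVs, the fitted models as
#' JSON, a manifest and a log, under stable file names. Percentages are
#' rounded table-style: calibration and risk summaries to 3 decimals,
#' category prevalences to 1. If the directory already holds a bundle, the
#' prior bundle is preserved under a timestamped subdirectory.
#'
#' @param report An `audit_report` from [run_pipeline()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_reports <- function(report, out_dir) {
  stopifnot(inherits(report, "audit_report"))
  if (dir.exists(out_dir) &&
      file.exists(file.path(out_dir, "manifest.json"))) {
    stamp <- format(Sys.time(), "previous-%Y%m%d-%H%M%OS3")
    old <- setdiff(list.files(out_dir), dir(out_dir, pattern = "^previous-"))
    dir.create(file.path(out_dir, stamp))
    file.rename(file.path(out_dir, old), file.path(out_dir, stamp, old))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  paths <- c(
    cohort = p("cohort.csv"),
    characteristics = p("table1_characteristics.csv"),
    calibration = p("table2_calibration.csv"),
    discrimination = p("table3_discrimination.csv"),
    category_prevalence = p("table4_category_prevalence.csv"),
    risk_summaries = p("table5_risk_summaries.csv"),
    reclassification = p("reclassification.csv"),
    cumulative_risks = p("cumulative_risks.csv"),
    weights = p("weights.csv"),
    models = p("models.json"),
    manifest = p("manifest.json"),
    log = p("run.log")
  )
  readr::write_csv(report$cohort, paths["cohort"], na = "")
  readr::write_csv(report$characteristics, paths["characteristics"])
  readr::write_csv(
    dplyr::mutate(report$calibration,
                  dplyr::across(c("eo_ratio", "eo_low", "eo_high"),
                                ~ round_half_up(.x, 3))),
    paths["calibration"])
  readr::write_csv(
    dplyr::mutate(report$discrimination,
                  dplyr::across(c("auc", "auc_low", "auc_high"),
                                ~ round_half_up(.x, 3))),
    paths["discrimination"])
  readr::write_csv(
    dplyr::mutate(report$category_prevalence,
                  weighted_pct = round_half_up(.data$weighted_pct, 1)),
    paths["category_prevalence"])
  readr::write_csv(
    dplyr::mutate(report$risk_summaries,
                  dplyr::across(c("median", "q25", "q75"),
                                ~ round_half_up(.x, 3))),
    paths["risk_summaries"])
  readr::write_csv(report$reclassification, paths["reclassification"])
  readr::write_csv(
    dplyr::select(report$cumulative_risks, "woman_id", "interval", "variant",
                  "risk_pct"),
    paths["cumulative_risks"])
  readr::write_csv(dplyr::select(report$weights, "woman_id", "weight"),
                   paths["weights"])
  serialize_models(report$fits$include_race, paths["models"])
  jsonlite::write_json(report$manifest, paths["manifest"],
                       auto_unbox = TRUE, digits = NA)
  writeLines(report$log, paths["log"])
  invisible(paths)
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report>\n")
  cat(sprintf("  cohort: %d exams (%d advanced)\n", nrow(x$cohort),
              sum(x$cohort$outcome == "advanced_cancer")))
  cat(sprintf("  variants: %s\n", paste(names(x$fits), collapse = ", ")))
  cat("  tables: characteristics, calibration, discrimination,",
      "category_prevalence, risk_summaries, reclassification\n")
  invisible(x)
}
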