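#' Plot expected/observed calibration ratios by group and model variant
#'
#' Point-range plot of E/O ratios with bootstrap intervals, one panel per
#' screening interval when present; the horizontal line at 1 marks perfect
#' mean calibration.
#'
#' @param calibration A calibration tibble as produced by [run_pipeline()]
#'   (columns `group`, `variant`, `eo_ratio`, `eo_low`, `eo_high`, and
#'   optionally `interval`).
#' @return A ggplot object.
#' @export
plot_calibration <- function(calibration) {
  p <- ggplot2::ggplot(
    dplyr::filter(calibration, !is.na(.data$eo_ratio)),
    ggplot2::aes(x = .data$group, y = .data$eo_ratio,
                 colour = .data$variant)
  ) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$eo_low, ymax = .data$eo_high),
      position = ggplot2::position_dodge(width = 0.5)
    ) +
    ggplot2::labs(x = NULL, y = "Expected / observed advanced cancers",
                  colour = "Model") +
    ggplot2::theme_minimal()
  if ("interval" %in% names(calibration)) {
    p <- p + ggplot2::facet_wrap(~interval)
  }
  p
}

#' Plot cumulative-risk distributions by race, variant and cancer status
#'
#' Violin-style summary of the cumulative 6-year risk distribution for each
#' race group under both model variants, faceted by advanced-cancer status.
#'
#' @param cumulative_risks Tibble with `risk_pct`, `variant`, `advanced` and
#'   a race column (`race` or `race_ethnicity`).
#' @return A ggplot object.
#' @export
plot_risk_distribution <- function(cumulative_risks) {
  race_col <- intersect(c("race", "race_ethnicity"),
                        names(cumulative_risks))[1L]
  df <- dplyr::mutate(
    cumulative_risks,
    status = ifelse(.data$advanced, "Advanced cancer", "No advanced cancer")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[race_col]],
                                   y = .data$risk_pct,
                                   fill = .data$variant)) +
    ggplot2::geom_violin(position = ggplot2::position_dodge(width = 0.8),
                         scale = "width", alpha = 0.7) +
    ggplot2::facet_wrap(~status, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Cumulative 6-year risk (%)",
                  fill = "Model") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot risk-category prevalence by race and variant
#'
#' @param prevalence A [category_prevalence()] table.
#' @return A ggplot object.
#' @export
plot_category_prevalence <- function(prevalence) {
  df <- dplyr::filter(prevalence, .data$variant != "difference")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$race, y = .data$weighted_pct,
                                   fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::facet_wrap(~variant) +
    ggplot2::labs(x = NULL, y = "Weighted % of women", fill = "Risk level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @describeIn fit_round_models Coefficient forest plot (first imputation).
#' @param object A `round_model_fit`.
#' @method autoplot round_model_fit
#' @export
autoplot.round_model_fit <- function(object, ...) {
  td <- dplyr::filter(tidy(object), .data$imputation == 1L,
                      .data$term != "(Intercept)",
                      !.data$term %in% c("age", "age_sq"))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error,
                   colour = .data$event)
    ) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = "Log odds ratio", y = NULL, colour = "Event") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
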