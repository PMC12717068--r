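# Internal helpers shared across modules.

# Derive a stage-specific seed from a master seed so that independent stages
# draw from non-overlapping streams. Kept below 2^31 - 1 for R's integer RNG.
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master_seed) * 7919 + h * 104729) %% 2147483629)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_prob_block <- function(p, block, tol = 1e-9) {
  if (any(!is.finite(p)) || any(p < 0)) {
    abort(sprintf("Probability block '%s' has negative or non-finite entries.",
                  block),
          class = "screenaudit_config_error")
  }
  if (abs(sum(p) - 1) > tol) {
    abort(sprintf("Probability block '%s' sums to %.12f, not 1.",
                  block, sum(p)),
          class = "screenaudit_config_error")
  }
  invisible(p)
}

# Draw one level per row from a matrix of row-wise category probabilities.
sample_levels <- function(prob_matrix, levels) {
  stopifnot(ncol(prob_matrix) == length(levels))
  u <- runif(nrow(prob_matrix))
  cum <- t(apply(prob_matrix, 1L, cumsum))
  idx <- rowSums(u > cum) + 1L
  levels[pmin(idx, length(levels))]
}

#' Weighted empirical quantile
#'
#' The p-th weighted percentile is the smallest observed value whose
#' cumulative normalized weight reaches `p`. This left-continuous
#' cumulative-weight rule is used everywhere the package computes percentile
#' thresholds, medians and interquartile ranges, so thresholds and summaries
#' are mutually consistent.
#'
#' @param x Numeric vector of observations.
#' @param w Nonnegative weights aligned with `x`; defaults to equal weights.
#' @param probs Probabilities in `[0, 1]`.
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @export
#' @examples
#' weighted_quantile(1:100, probs = c(0.05, 0.25, 0.75, 0.95))
weighted_quantile <- function(x, w = NULL, probs) {
  if (length(x) == 0L) abort("weighted_quantile(): empty input.")
  if (is.null(w)) w <- rep(1, length(x))
  stopifnot(length(w) == length(x), all(w >= 0), any(w > 0),
            all(probs >= 0), all(probs <= 1))
  ord <- order(x)
  xs <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) {
    xs[which(cw >= p - 1e-12)[1L]]
  }, numeric(1))
}

inv_logit <- function(x) plogis(x)

round_half_up <- function(x, digits = 0) {
  # Commercial rounding used for printed-table style percentages, so that
  # e.g. 0.125 prints as 0.13 rather than banker's-rounded 0.12.
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5 + 1e-9) / p
}

as_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != floor(x)) {
    abort(sprintf("'%s' must be a single positive integer.", name),
          class = "screenaudit_config_error")
  }
  as.integer(x)
}
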