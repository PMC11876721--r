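#' Variance-explained effect size (partial eta squared)
#'
#' Partitions the subject-level contrast maps, averaged over a time window,
#' as in a one-sample ANOVA: with `c_s` the window-mean contrast map of
#' subject `s` and `g` their grand mean,
#' `SS_effect = N * sum_ch(g^2)` (variance explained by the design) and
#' `SS_error = sum_s sum_ch((c_s - g)^2)` (residual subject variability),
#' giving `eta2 = SS_effect / (SS_effect + SS_error)`. With no residual
#' variability eta2 -> 1; with no effect and many subjects eta2 -> 0.
#'
#' @param erps A `condition_erp` tibble.
#' @param effect Contrast to evaluate (see [tanova_pointwise()]).
#' @param window_ms Length-2 analysis window in ms.
#' @param normalized Normalize maps to unit GFP per timepoint first.
#' @param sets For `between_sets`: the two cell labels.
#' @return Partial eta squared in `[0, 1)`.
#' @export
effect_size_eta2 <- function(erps, effect = tanova_effects, window_ms,
                             normalized = FALSE, sets = NULL) {
  effect <- match.arg(effect)
  cmaps <- subject_contrast_maps(erps, effect, window_ms, normalized, sets)
  g <- colMeans(cmaps)
  ss_eff <- nrow(cmaps) * sum(g^2)
  ss_err <- sum(sweep(cmaps, 2, g)^2)
  if (ss_eff + ss_err <= 0) rlang::abort("zero total variance in the contrast maps")
  ss_eff / (ss_eff + ss_err)
}

# window-mean contrast map per subject (rows subjects x cols channels)
subject_contrast_maps <- function(erps, effect, window_ms, normalized, sets) {
  times <- erp_times(erps)
  idx <- which(times >= window_ms[1] & times <= window_ms[2])
  if (length(idx) == 0) rlang::abort("`window_ms` contains no samples")
  if (effect == "between_sets") {
    cells <- sets %||% unique(erps$cell)
    if (length(cells) != 2) rlang::abort("`between_sets` compares exactly two conditions")
    coef1 <- c(1, -1)
  } else {
    cells <- c("Exp_Rep", "Unexp_Alt", "Unexp_Rep", "Exp_Alt")
    info <- tibble::tibble(is_repetition = grepl("Rep$", cells),
                           is_expected = grepl("^Exp", cells))
    coef1 <- factorial_coef(effect, info)
  }
  subjects <- sort(unique(erps$subject))
  t(vapply(subjects, function(s) {
    maps <- lapply(cells, function(cl) {
      m <- erps$map[[which(erps$subject == s & erps$cell == cl)]]
      m <- if (normalized) normalize_by_gfp(m[, idx, drop = FALSE]) else m[, idx, drop = FALSE]
      rowMeans(m)
    })
    Reduce(`+`, Map(`*`, maps, coef1))
  }, numeric(nrow(erps$map[[1]]))))
}

#' Convert partial eta squared to Cohen's d
#'
#' Deterministic conversion `d = 2 * sqrt(eta2 / (1 - eta2))`, the standard
#' relation between variance explained and a standardized two-level mean
#' difference; values are rounded to two decimals for reporting.
#'
#' @param eta2 Partial eta squared, in `[0, 1)`.
#' @param digits Reporting precision (default 2; `NULL` for unrounded).
#' @return Cohen's d (vectorized over `eta2`).
#' @examples
#' eta2_to_cohens_d(0.25) # 1.15
#' @export
eta2_to_cohens_d <- function(eta2, digits = 2) {
  if (any(!is.finite(eta2)) || any(eta2 < 0) || any(eta2 >= 1)) {
    rlang::abort("`eta2` must lie in [0, 1)")
  }
  d <- 2 * sqrt(eta2 / (1 - eta2))
  if (is.null(digits)) d else round(d, digits)
}

#' Permutation-based z-score and Cohen's d over a window
#'
#' Compares the observed statistic, averaged over the window, with the
#' permutation distribution of window-mean statistics:
#' `z = (observed - mean(perm)) / sd(perm)`, then normalizes by the square
#' root of the product of the condition proportions and the sample size:
#' `d = z / sqrt(p1 * p2 * N)`.
#'
#' @param result A `tanova_result` with retained permutation statistics.
#' @param window_ms Length-2 window in ms (defaults to the full epoch).
#' @param p1,p2 Condition proportions (default 0.5 each).
#' @param n_subjects Sample size `N`; defaults to the fitted value.
#' @return A tibble with `z_score` and `cohen_d`.
#' @export
cohens_d_permutation <- function(result, window_ms = NULL, p1 = 0.5, p2 = 0.5,
                                 n_subjects = NULL) {
  stopifnot(inherits(result, "tanova_result"))
  if (is.null(result$perm_stats)) rlang::abort("permutation statistics were not retained")
  n_subjects <- n_subjects %||% result$n_subjects
  idx <- if (is.null(window_ms)) {
    seq_along(result$times_ms)
  } else {
    which(result$times_ms >= window_ms[1] & result$times_ms <= window_ms[2])
  }
  if (length(idx) == 0) rlang::abort("`window_ms` contains no samples")
  obs <- mean(result$observed[idx])
  perm <- rowMeans(result$perm_stats[, idx, drop = FALSE])
  s <- stats::sd(perm)
  if (s <= 0) rlang::abort("zero permutation variance over the window")
  z <- (obs - mean(perm)) / s
  tibble::tibble(z_score = z, cohen_d = z / sqrt(p1 * p2 * n_subjects))
}
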