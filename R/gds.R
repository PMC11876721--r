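#' Maximal runs of significant timepoints
#'
#' Finds the maximal segments of strictly consecutive samples with
#' `p < alpha`. A single sample at or above `alpha` breaks a run (no gap
#' bridging). Durations are reported both in samples and in ms (samples
#' times the sampling period).
#'
#' @param p_series Per-timepoint p-values.
#' @param alpha Significance level (default 0.05).
#' @param times_ms Optional sample times; defaults to sample indices.
#' @return A tibble with one row per run: `onset_ms`, `offset_ms`,
#'   `n_samples`, `duration_ms`.
#' @export
runs_below_alpha <- function(p_series, alpha = 0.05, times_ms = NULL) {
  if (length(p_series) == 0) rlang::abort("`p_series` is empty")
  times_ms <- times_ms %||% seq_along(p_series)
  dt <- if (length(times_ms) > 1) stats::median(diff(times_ms)) else 1
  r <- rle(p_series < alpha)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sig <- which(r$values)
  tibble::tibble(
    onset_ms = times_ms[starts[sig]],
    offset_ms = times_ms[ends[sig]],
    n_samples = r$lengths[sig],
    duration_ms = r$lengths[sig] * dt
  )
}

max_run_length <- function(x) {
  # longest run of TRUE in a logical vector
  r <- rle(x)
  runs <- r$lengths[r$values]
  if (length(runs) == 0) 0L else max(runs)
}

#' Per-permutation p-value series
#'
#' Re-ranks every permutation statistic within its timepoint's permutation
#' distribution, treating it as if it were the observed value:
#' `p_k(t) = (1 + #\{j != k: perm[j,t] >= perm[k,t]\}) / (1 + n_perm)`.
#' These series carry the null distribution of significant-run durations
#' without any new resampling.
#'
#' @param result A `tanova_result` with retained permutation statistics.
#' @return An `n_perm` x timepoints matrix of p-values.
#' @export
permutation_p_series <- function(result) {
  stopifnot(inherits(result, "tanova_result"))
  if (is.null(result$perm_stats)) rlang::abort("permutation statistics were not retained")
  ps <- result$perm_stats
  n <- nrow(ps)
  # #{j != k: v_j >= v_k} = n - rank_min(v_k); ties count as exceedances
  ranks <- apply(ps, 2, rank, ties.method = "min")
  (1 + n - ranks) / (1 + n)
}

#' Global duration statistics (GDS) correction
#'
#' Duration-based control of the family-wise error rate over the epoch: the
#' duration threshold is the given percentile (ceiling-rank quantile, as
#' run lengths are heavily tied integers) of the per-permutation maximum
#' run length of `p < alpha`, and an observed run survives only if its
#' duration strictly exceeds that threshold.
#'
#' @param result A `tanova_result` with retained permutation statistics.
#' @param alpha Pointwise significance level (default 0.05).
#' @param percentile Percentile of the null maximum-run distribution
#'   (default 95).
#' @return A `gds_result`: observed runs with a `surviving` flag, the
#'   duration threshold (samples and ms), and the permutation maximum-run
#'   distribution.
#' @export
apply_gds <- function(result, alpha = 0.05, percentile = 95) {
  stopifnot(inherits(result, "tanova_result"))
  perm_p <- permutation_p_series(result)
  max_runs <- apply(perm_p < alpha, 1, max_run_length)
  threshold <- as.integer(stats::quantile(max_runs, percentile / 100, type = 1))
  dt <- if (length(result$times_ms) > 1) stats::median(diff(result$times_ms)) else 1
  runs <- runs_below_alpha(result$p, alpha, result$times_ms)
  runs$surviving <- runs$n_samples > threshold
  structure(list(effect = result$effect, alpha = alpha, percentile = percentile,
                 duration_threshold_samples = threshold,
                 duration_threshold_ms = threshold * dt,
                 runs = runs, perm_max_run_distribution = max_runs,
                 times_ms = result$times_ms, n_perm = result$n_perm),
            class = "gds_result")
}

#' @export
print.gds_result <- function(x, ...) {
  surv <- x$runs[x$runs$surviving, , drop = FALSE]
  cat(sprintf("<gds_result> effect %s: duration threshold %d samples (%.1f ms), %d/%d run(s) surviving\n",
              x$effect, x$duration_threshold_samples, x$duration_threshold_ms,
              nrow(surv), nrow(x$runs)))
  if (nrow(surv) > 0) {
    for (i in seq_len(nrow(surv))) {
      cat(sprintf("  %g..%g ms (%d samples)\n", surv$onset_ms[i],
                  surv$offset_ms[i], surv$n_samples[i]))
    }
  }
  invisible(x)
}
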