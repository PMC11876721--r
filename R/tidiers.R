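#' Tidy a TANOVA result
#'
#' @param x A `tanova_result`.
#' @param ... Unused.
#' @return A tibble with one row per timepoint: `time_ms`, `statistic`
#'   (the observed global dissimilarity), `p_value`.
#' @method tidy tanova_result
#' @export
tidy.tanova_result <- function(x, ...) {
  tibble::tibble(effect = x$effect, time_ms = x$times_ms,
                 statistic = x$observed, p_value = x$p)
}

#' @rdname tidy.tanova_result
#' @method glance tanova_result
#' @export
glance.tanova_result <- function(x, ...) {
  tibble::tibble(effect = x$effect, n_timepoints = length(x$p),
                 n_perm = x$n_perm, n_subjects = x$n_subjects,
                 normalized = x$normalized, min_p = min(x$p),
                 n_significant = sum(x$p < x$alpha), alpha = x$alpha)
}

#' Tidy a GDS result
#'
#' @param x A `gds_result`.
#' @param ... Unused.
#' @return The runs tibble (`onset_ms`, `offset_ms`, `n_samples`,
#'   `duration_ms`, `surviving`).
#' @method tidy gds_result
#' @export
tidy.gds_result <- function(x, ...) {
  dplyr::mutate(x$runs, effect = x$effect, .before = 1)
}

#' @rdname tidy.gds_result
#' @method glance gds_result
#' @export
glance.gds_result <- function(x, ...) {
  tibble::tibble(effect = x$effect, alpha = x$alpha,
                 percentile = x$percentile,
                 duration_threshold_samples = x$duration_threshold_samples,
                 duration_threshold_ms = x$duration_threshold_ms,
                 n_runs = nrow(x$runs), n_surviving = sum(x$runs$surviving))
}

#' Tidy a factorial analysis
#'
#' @param x A `factorial_analysis`.
#' @param ... Unused.
#' @return The windows tibble across all three effects.
#' @method tidy factorial_analysis
#' @export
tidy.factorial_analysis <- function(x, ...) x$windows

#' @rdname tidy.factorial_analysis
#' @method glance factorial_analysis
#' @export
glance.factorial_analysis <- function(x, ...) {
  dplyr::bind_rows(lapply(x$gds, glance))
}
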