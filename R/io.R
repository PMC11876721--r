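# All persistence is plain text: delimited matrices for numeric data, YAML
# sidecars for metadata, JSON for the summary report.

#' Write / read epoched data
#'
#' One subject's epochs are stored as a delimited matrix of
#' `trials * time` rows by channels (trial-major) in `<prefix>_data.csv`,
#' the trial table in `<prefix>_trials.csv`, and labels, sampling rate,
#' epoch window, units and seed in `<prefix>_meta.yaml`.
#'
#' @param epochs An `erp_epochs` object.
#' @param prefix Path prefix for the three files.
#' @return `write_epochs()` returns `prefix` invisibly; `read_epochs()` the
#'   reconstructed `erp_epochs`.
#' @export
write_epochs <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "erp_epochs"))
  d <- epochs$data
  n_trials <- dim(d)[1]; n_ch <- dim(d)[2]; n_t <- dim(d)[3]
  flat <- matrix(aperm(d, c(3, 1, 2)), n_trials * n_t, n_ch) # time within trial
  colnames(flat) <- epochs$montage$channel
  readr::write_csv(tibble::as_tibble(flat), paste0(prefix, "_data.csv"))
  write_trial_table(epochs$trial_table, paste0(prefix, "_trials.csv"))
  meta <- list(subject_id = epochs$subject_id,
               sampling_rate = epochs$sampling_rate,
               times_ms = as.numeric(epochs$times_ms),
               units = "microvolt",
               seed = as.integer(epochs$seed),
               n_trials = n_trials,
               channels = epochs$montage$channel,
               montage_x = epochs$montage$x,
               montage_y = epochs$montage$y)
  yaml::write_yaml(meta, paste0(prefix, "_meta.yaml"), precision = 15)
  invisible(prefix)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yaml"))
  flat <- as.matrix(readr::read_csv(paste0(prefix, "_data.csv"),
                                    show_col_types = FALSE))
  trials <- read_trial_table(paste0(prefix, "_trials.csv"))
  n_t <- length(meta$times_ms)
  n_trials <- meta$n_trials
  d <- aperm(array(flat, c(n_t, n_trials, ncol(flat))), c(2, 3, 1))
  montage <- tibble::tibble(channel = meta$channels,
                            x = meta$montage_x, y = meta$montage_y)
  dimnames(d) <- list(NULL, montage$channel, NULL)
  new_erp_epochs(d, meta$times_ms, meta$sampling_rate, montage, trials,
                 subject_id = meta$subject_id,
                 seed = meta$seed %||% NA_integer_)
}

#' Write / read subject-by-condition ERP maps
#'
#' Each subject x cell map is one channels x time CSV (channel label in the
#' first column) under `dir`, indexed by `meta.yaml`. `read_condition_erps()`
#' also serves as the loader for pre-averaged ERPs from real recordings, so
#' datasets can enter the statistics without simulation.
#'
#' @param erps A `condition_erp` tibble.
#' @param dir Output directory (created if needed).
#' @return `write_condition_erps()` returns `dir` invisibly;
#'   `read_condition_erps()` the `condition_erp` tibble.
#' @export
write_condition_erps <- function(erps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- tibble::as_tibble(erps)[, c("subject", "category", "cell",
                                     "is_repetition", "is_expected", "n_trials")]
  idx$file <- sprintf("%s_%s_%s.csv", idx$subject,
                      ifelse(is.na(idx$category), "none", idx$category),
                      idx$cell)
  for (i in seq_len(nrow(erps))) {
    m <- erps$map[[i]]
    out <- tibble::as_tibble(m, .name_repair = ~ sprintf("t%04d", seq_along(.x)))
    out <- dplyr::bind_cols(tibble::tibble(channel = rownames(m)), out)
    readr::write_csv(out, file.path(dir, idx$file[i]))
  }
  montage <- erp_montage(erps)
  meta <- list(times_ms = as.numeric(erp_times(erps)),
               units = "microvolt",
               index = lapply(seq_len(nrow(idx)), function(i) as.list(idx[i, ])),
               channels = if (!is.null(montage)) montage$channel,
               montage_x = if (!is.null(montage)) montage$x,
               montage_y = if (!is.null(montage)) montage$y)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"), precision = 15)
  invisible(dir)
}

#' @rdname write_condition_erps
#' @export
read_condition_erps <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  rows <- purrr::map_dfr(meta$index, function(r) {
    tibble::as_tibble(lapply(r, function(v) if (is.null(v)) NA else v))
  })
  rows$map <- purrr::map(rows$file, function(f) {
    tab <- readr::read_csv(file.path(dir, f), show_col_types = FALSE)
    m <- as.matrix(tab[, -1])
    rownames(m) <- tab$channel
    colnames(m) <- NULL
    m
  })
  rows$file <- NULL
  rows$category <- as.character(rows$category)
  rows$category[rows$category == "none"] <- NA_character_
  montage <- if (!is.null(meta$channels)) {
    tibble::tibble(channel = meta$channels, x = meta$montage_x, y = meta$montage_y)
  }
  new_condition_erp(rows, meta$times_ms, montage)
}

#' Write a TANOVA result
#'
#' The observed statistic and p-value series go to `<prefix>.csv`, metadata
#' to `<prefix>.yaml`; `keep_perm = TRUE` additionally stores the
#' permutation statistic matrix as `<prefix>_perm.csv` for audit.
#'
#' @param result A `tanova_result`.
#' @param prefix Path prefix.
#' @param keep_perm Also persist the permutation statistics (large).
#' @return `prefix`, invisibly.
#' @export
write_tanova <- function(result, prefix, keep_perm = FALSE) {
  stopifnot(inherits(result, "tanova_result"))
  readr::write_csv(tidy(result), paste0(prefix, ".csv"))
  meta <- list(effect = result$effect, n_perm = result$n_perm,
               seed = result$seed, alpha = result$alpha,
               n_subjects = result$n_subjects, normalized = result$normalized,
               window_ms = result$window_ms)
  yaml::write_yaml(meta, paste0(prefix, ".yaml"))
  if (keep_perm) {
    readr::write_csv(tibble::as_tibble(result$perm_stats,
                                       .name_repair = ~ sprintf("t%04d", seq_along(.x))),
                     paste0(prefix, "_perm.csv"))
  }
  invisible(prefix)
}

#' Write a GDS result
#'
#' Runs (with the surviving flag) to `<prefix>_runs.csv`, threshold and
#' parameters to `<prefix>.yaml`.
#'
#' @param x A `gds_result`.
#' @param prefix Path prefix.
#' @return `prefix`, invisibly.
#' @export
write_gds <- function(x, prefix) {
  stopifnot(inherits(x, "gds_result"))
  readr::write_csv(x$runs, paste0(prefix, "_runs.csv"))
  yaml::write_yaml(list(effect = x$effect, alpha = x$alpha,
                        percentile = x$percentile,
                        duration_threshold_samples = x$duration_threshold_samples,
                        duration_threshold_ms = x$duration_threshold_ms,
                        n_perm = x$n_perm),
                   paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' Write a factorial analysis to a results directory
#'
#' Produces `windows.csv` (all runs of all effects), `effect_sizes.csv`
#' (surviving windows), one `tanova_<effect>.csv` per effect, and a
#' `report.json` summary.
#'
#' @param analysis A `factorial_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis_results <- function(analysis, dir) {
  stopifnot(inherits(analysis, "factorial_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(analysis$windows, file.path(dir, "windows.csv"))
  readr::write_csv(analysis$effect_sizes, file.path(dir, "effect_sizes.csv"))
  for (e in names(analysis$tanova)) {
    readr::write_csv(tidy(analysis$tanova[[e]]),
                     file.path(dir, sprintf("tanova_%s.csv", e)))
  }
  surviving <- analysis$windows[isTRUE_vec(analysis$windows$surviving), , drop = FALSE]
  report <- list(
    category = analysis$category,
    config = unclass(analysis$config),
    duration_thresholds_samples = lapply(analysis$gds, function(g) g$duration_threshold_samples),
    surviving_windows = surviving,
    effect_sizes = analysis$effect_sizes
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}

isTRUE_vec <- function(x) !is.na(x) & x
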