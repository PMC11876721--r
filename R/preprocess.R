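# Subject x condition averaged ERP maps: a tibble with one row per
# subject/cell and a channels x time matrix in the `map` list-column.
# Sample times and the montage travel as attributes; erp_times() and
# erp_montage() read them back.

new_condition_erp <- function(tbl, times_ms, montage) {
  tbl <- tibble::as_tibble(tbl)
  stopifnot(all(c("subject", "cell", "map") %in% names(tbl)))
  attr(tbl, "times_ms") <- times_ms
  attr(tbl, "montage") <- montage
  class(tbl) <- unique(c("condition_erp", class(tbl)))
  tbl
}

#' Sample times and montage of a condition-ERP table
#'
#' @param erps A `condition_erp` tibble (from [average_conditions()],
#'   [simulate_condition_erps()] or [read_condition_erps()]).
#' @return `erp_times()` the vector of sample times in ms; `erp_montage()`
#'   the montage tibble.
#' @export
erp_times <- function(erps) {
  t <- attr(erps, "times_ms")
  if (is.null(t)) rlang::abort("no `times_ms` attribute; rebuild with as_condition_erp()")
  t
}

#' @rdname erp_times
#' @export
erp_montage <- function(erps) attr(erps, "montage")

#' @rdname erp_times
#' @param tbl A plain tibble with `subject`, `cell` and `map` columns.
#' @param times_ms Sample times in ms.
#' @param montage Montage tibble.
#' @export
as_condition_erp <- function(tbl, times_ms, montage = NULL) {
  new_condition_erp(tbl, times_ms, montage)
}

# ---- filtering ----------------------------------------------------------

# zero-phase filtering of each column of x with odd-reflection padding at
# both ends (signal::filtfilt pads nothing, which distorts short epochs)
zero_phase <- function(b, a, x) {
  n <- nrow(x)
  pad <- n - 1L
  top <- 2 * x[rep(1L, pad), , drop = FALSE] - x[(pad + 1L):2L, , drop = FALSE]
  bot <- 2 * x[rep(n, pad), , drop = FALSE] - x[(n - 1L):(n - pad), , drop = FALSE]
  ext <- rbind(top, x, bot)
  y <- apply(ext, 2, function(col) {
    f <- signal::filter(b, a, col)
    rev(signal::filter(b, a, rev(f)))
  })
  y[pad + seq_len(n), , drop = FALSE]
}

#' Band-pass filter epoched data
#'
#' Cascade of a high-pass and a low-pass Butterworth filter of the given
#' order, each applied forward and backward (zero phase), so the effective
#' amplitude response at frequency f is the squared magnitude of the
#' analog prototype. Epoch edges are padded by odd reflection to control
#' transients.
#'
#' @param x An `erp_epochs` object or a time x series numeric matrix.
#' @param low_hz,high_hz Band edges in Hz.
#' @param order Butterworth order of each section (default 4).
#' @param sampling_rate Required when `x` is a plain matrix.
#' @return Object of the same form with filtered signals.
#' @export
bandpass_filter <- function(x, low_hz = 0.3, high_hz = 30, order = 4,
                            sampling_rate = NULL) {
  if (!(low_hz >= 0 && high_hz > low_hz)) rlang::abort("invalid band edges")
  if (inherits(x, "erp_epochs")) {
    fs <- x$sampling_rate
    if (fs <= 2 * high_hz) rlang::abort("sampling rate must exceed twice the upper band edge")
    d <- x$data
    n_trials <- dim(d)[1]; n_ch <- dim(d)[2]; n_t <- dim(d)[3]
    m <- matrix(aperm(d, c(3, 2, 1)), n_t, n_ch * n_trials)
    m <- bandpass_matrix(m, low_hz, high_hz, order, fs)
    x$data <- aperm(array(m, c(n_t, n_ch, n_trials)), c(3, 2, 1))
    dimnames(x$data) <- list(NULL, x$montage$channel, NULL)
    return(x)
  }
  if (is.null(sampling_rate)) rlang::abort("`sampling_rate` is required for matrix input")
  if (sampling_rate <= 2 * high_hz) rlang::abort("sampling rate must exceed twice the upper band edge")
  one_col <- is.null(dim(x))
  m <- if (one_col) matrix(x, ncol = 1) else x
  out <- bandpass_matrix(m, low_hz, high_hz, order, sampling_rate)
  if (one_col) drop(out) else out
}

bandpass_matrix <- function(m, low_hz, high_hz, order, fs) {
  hp <- signal::butter(order, low_hz / (fs / 2), type = "high")
  lp <- signal::butter(order, high_hz / (fs / 2), type = "low")
  m <- zero_phase(hp$b, hp$a, m)
  zero_phase(lp$b, lp$a, m)
}

# ---- reference / baseline / rejection -----------------------------------

#' Re-reference to the average reference
#'
#' Subtracts the mean across channels at every timepoint; idempotent.
#'
#' @param x An `erp_epochs` object, a `condition_erp` tibble, or a
#'   channels x time matrix.
#' @return Same form as the input.
#' @export
average_reference <- function(x) {
  if (inherits(x, "erp_epochs")) {
    means <- apply(x$data, c(1, 3), mean) # trials x time
    x$data <- x$data - aperm(array(means, c(dim(x$data)[1], dim(x$data)[3], dim(x$data)[2])),
                             c(1, 3, 2))
    return(x)
  }
  if (inherits(x, "condition_erp")) {
    x$map <- purrr::map(x$map, function(m) sweep(m, 2, colMeans(m)))
    return(x)
  }
  if (nrow(x) < 2) rlang::abort("average reference needs at least 2 channels")
  sweep(x, 2, colMeans(x))
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline window, so
#' the baseline segment averages to zero afterwards.
#'
#' @param epochs An `erp_epochs` object.
#' @param window_ms Baseline window (default `c(-150, 0)`).
#' @return The corrected `erp_epochs`.
#' @export
baseline_correct <- function(epochs, window_ms = c(-150, 0)) {
  stopifnot(inherits(epochs, "erp_epochs"))
  idx <- which(epochs$times_ms >= window_ms[1] & epochs$times_ms <= window_ms[2])
  if (length(idx) == 0) rlang::abort("baseline window contains no samples")
  base <- apply(epochs$data[, , idx, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - array(base, dim = dim(epochs$data))
  epochs
}

#' Reject trials by amplitude threshold
#'
#' A trial is removed iff any sample in any channel strictly exceeds the
#' threshold in absolute value (a peak exactly at the threshold is kept).
#'
#' @param epochs An `erp_epochs` object.
#' @param threshold_uv Rejection threshold in microvolts (default 80).
#' @return A list with the pruned `epochs` and a `log` tibble recording the
#'   per-trial peak amplitude and decision.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 80) {
  stopifnot(inherits(epochs, "erp_epochs"), threshold_uv > 0)
  peak <- apply(abs(epochs$data), 1, max)
  rejected <- peak > threshold_uv
  log <- tibble::tibble(trial_index = epochs$trial_table$trial_index,
                        max_abs_uv = peak, rejected = rejected)
  epochs$data <- epochs$data[!rejected, , , drop = FALSE]
  epochs$trial_table <- epochs$trial_table[!rejected, ]
  list(epochs = epochs, log = log)
}

#' Average trials into subject x condition ERPs
#'
#' Arithmetic mean over the surviving trials of each design cell,
#' excluding target trials by default (only nontarget trials enter the
#' formal statistics).
#'
#' @param epochs An `erp_epochs` object.
#' @param nontarget_only Drop target trials before averaging (default TRUE).
#' @param by Grouping columns of the trial table (default category + cell).
#' @param require_complete Error if any cell of the canonical 2x2 design has
#'   no surviving trials (default TRUE; set FALSE for subsetted data).
#' @return A `condition_erp` tibble with columns `subject`, `category`,
#'   `cell`, `is_repetition`, `is_expected`, `n_trials` and the `map`
#'   list-column (channels x time).
#' @export
average_conditions <- function(epochs, nontarget_only = TRUE,
                               by = c("category", "cell"),
                               require_complete = TRUE) {
  stopifnot(inherits(epochs, "erp_epochs"))
  tab <- epochs$trial_table
  keep <- if (nontarget_only) !tab$is_target else rep(TRUE, nrow(tab))
  tab <- tab[keep, ]
  data <- epochs$data[keep, , , drop = FALSE]
  groups <- dplyr::distinct(tab[, by, drop = FALSE])
  # for the canonical 2x2 design every cell must survive rejection
  canonical <- c("Exp_Rep", "Exp_Alt", "Unexp_Rep", "Unexp_Alt")
  if (require_complete && "cell" %in% by && all(tab$cell %in% canonical)) {
    full <- dplyr::distinct(tab[, setdiff(by, "cell"), drop = FALSE])
    full <- if (ncol(full) == 0) {
      tibble::tibble(cell = canonical)
    } else {
      tidyr::crossing(full, cell = canonical)
    }
    missing <- dplyr::anti_join(full, groups, by = by)
    if (nrow(missing) > 0) {
      rlang::abort(sprintf("no surviving trials in cell %s",
                           paste(unlist(missing[1, ]), collapse = "/")))
    }
  }
  for (i in seq_len(nrow(groups))) {
    sel <- rep(TRUE, nrow(tab))
    for (col in by) sel <- sel & tab[[col]] == groups[[col]][i]
    if (!any(sel)) {
      rlang::abort(sprintf("no surviving trials in cell %s",
                           paste(unlist(groups[i, ]), collapse = "/")))
    }
  }
  rows <- purrr::map(seq_len(nrow(groups)), function(i) {
    sel <- rep(TRUE, nrow(tab))
    for (col in by) sel <- sel & tab[[col]] == groups[[col]][i]
    m <- apply(data[sel, , , drop = FALSE], c(2, 3), mean)
    rownames(m) <- epochs$montage$channel
    out <- groups[i, ]
    out$subject <- epochs$subject_id
    out$is_repetition <- if ("cell" %in% by) grepl("Rep$", out$cell) else NA
    out$is_expected <- if ("cell" %in% by) grepl("^Exp", out$cell) else NA
    out$n_trials <- sum(sel)
    out$map <- list(m)
    out
  })
  erps <- dplyr::bind_rows(rows)
  if (!"category" %in% names(erps)) erps$category <- NA_character_
  erps <- erps[, c("subject", "category", "cell", "is_repetition",
                   "is_expected", "n_trials", "map")]
  new_condition_erp(erps, epochs$times_ms, epochs$montage)
}

#' Combine condition-ERP tables from several subjects
#'
#' @param ... `condition_erp` tibbles (or a single list of them).
#' @return One `condition_erp` tibble.
#' @export
bind_condition_erps <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && !inherits(args[[1]], "condition_erp")) {
    args <- args[[1]]
  }
  times <- erp_times(args[[1]])
  montage <- erp_montage(args[[1]])
  new_condition_erp(dplyr::bind_rows(lapply(args, tibble::as_tibble)),
                    times, montage)
}
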