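#' Global field power
#'
#' Standard deviation of voltage across channels at one timepoint (with the
#' population divisor): `sqrt(mean((v - mean(v))^2))`. A reference-free
#' measure of overall map strength.
#'
#' @param map Numeric channel vector, or a channels x time matrix (one GFP
#'   per column).
#' @return Scalar (vector input) or per-timepoint vector (matrix input), uV.
#' @export
gfp <- function(map) {
  if (is.matrix(map)) {
    sqrt(colMeans(sweep(map, 2, colMeans(map))^2))
  } else {
    sqrt(mean((map - mean(map))^2))
  }
}

#' Global dissimilarity index between two scalp maps
#'
#' Root of the channel-averaged squared voltage difference:
#' `sqrt(mean((a - b)^2))`. For average-referenced maps this equals the GFP
#' of the difference map. Symmetric and nonnegative.
#'
#' @param a,b Channel vectors (or channels x time matrices) with identical
#'   channel sets.
#' @return Scalar dissimilarity in uV (or per-timepoint vector).
#' @export
gdi <- function(a, b) {
  if (!identical(dim(a), dim(b)) || length(a) != length(b)) {
    rlang::abort("maps must share the same channels (and timepoints)")
  }
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b))) {
    rlang::abort("channel labels of the two maps differ")
  }
  d <- a - b
  if (is.matrix(d)) sqrt(colMeans(d^2)) else sqrt(mean(d^2))
}

#' Normalize a map series to unit global field power
#'
#' Divides each timepoint's map by its GFP, removing overall amplitude so
#' that only topography differences remain (the McCarthy--Wood style
#' normalization used before pure topography contrasts).
#'
#' @param map_series Channels x time matrix (a single channel vector is
#'   treated as one timepoint).
#' @param tol GFP below `tol` counts as a flat map and raises an error
#'   naming the timepoint.
#' @return Matrix (or vector) with `gfp() == 1` at every timepoint.
#' @export
normalize_by_gfp <- function(map_series, tol = 1e-12) {
  vec <- !is.matrix(map_series)
  m <- if (vec) matrix(map_series, ncol = 1) else map_series
  g <- gfp(m)
  if (any(g < tol)) {
    rlang::abort(sprintf("flat map (GFP == 0) at timepoint index %d cannot be normalized",
                         which(g < tol)[1]))
  }
  out <- sweep(m, 2, g, "/")
  if (vec) stats::setNames(drop(out), names(map_series)) else out
}

# ---- TANOVA core ---------------------------------------------------------

tanova_effects <- c("repetition_main", "expectation_main", "interaction",
                    "between_sets")

# contrast coefficients over a subject's cells (rows of `info`)
factorial_coef <- function(effect, info) {
  s_rep <- 2 * info$is_repetition - 1
  s_exp <- 2 * info$is_expected - 1
  switch(effect,
    repetition_main  = s_rep / 2,
    expectation_main = s_exp / 2,
    interaction      = s_rep * s_exp # unscaled double difference
  )
}

perms_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Monte-Carlo permutation engine. M: (n_subjects*k) x (n_ch*n_t) matrix with
# rows grouped by subject, columns time-major (channel blocks fastest is NOT
# used; layout is [t within channel]); coef: per-row contrast coefficients.
# scheme "full_cell" uniformly permutes each subject's k cell labels;
# "restricted" flips only the tested factor within levels of the other one
# (strata supplied as a per-row integer).
tanova_engine <- function(M, coef, n_subjects, k, n_ch, n_t, n_perm, seed,
                          scheme = "full_cell", strata = NULL,
                          chunk = 500L) {
  rms_by_time <- function(P) {
    # P: n x (n_ch*n_t), columns ordered channel-fastest within timepoint
    P2 <- P * P
    out <- matrix(0, nrow(P), n_t)
    for (c in seq_len(n_ch)) {
      out <- out + P2[, (seq_len(n_t) - 1L) * n_ch + c, drop = FALSE]
    }
    sqrt(out / n_ch)
  }
  obs_vec <- crossprod(M, coef) / n_subjects
  observed <- drop(rms_by_time(matrix(obs_vec, nrow = 1)))

  all_perms <- perms_of(k)
  perm_stats <- matrix(NA_real_, n_perm, n_t)
  withr_seed(seed, {
    done <- 0L
    while (done < n_perm) {
      nb <- min(chunk, n_perm - done)
      W <- matrix(0, nb, n_subjects * k)
      for (b in seq_len(nb)) {
        w <- numeric(n_subjects * k)
        for (s in seq_len(n_subjects)) {
          rows <- (s - 1L) * k + seq_len(k)
          if (scheme == "full_cell") {
            pi_s <- all_perms[sample.int(nrow(all_perms), 1L), ]
            w[rows] <- coef[rows][pi_s]
          } else {
            w[rows] <- coef[rows]
            for (g in unique(strata[rows])) {
              idx <- rows[strata[rows] == g]
              if (stats::runif(1) < 0.5) w[idx] <- rev(w[idx]) # swap the pair
            }
          }
        }
        W[b, ] <- w
      }
      perm_stats[done + seq_len(nb), ] <- rms_by_time((W %*% M) / n_subjects)
      done <- done + nb
    }
  })
  # ties count as exceedances; allow for last-bit rounding differences
  # between the observed (matrix-vector) and permuted (matrix-matrix) paths
  tol <- 1e-9 * (abs(observed) + 1e-12)
  p <- (1 + colSums(perm_stats >= matrix(observed - tol, n_perm, n_t, byrow = TRUE))) /
    (1 + n_perm)
  list(observed = observed, p = p, perm_stats = perm_stats)
}

# stack a condition_erp table into the engine layout; maps optionally
# GFP-normalized per timepoint first
stack_maps <- function(erps, cell_order, normalized) {
  subjects <- sort(unique(erps$subject))
  k <- length(cell_order)
  n_ch <- nrow(erps$map[[1]])
  n_t <- ncol(erps$map[[1]])
  M <- matrix(NA_real_, length(subjects) * k, n_ch * n_t)
  for (si in seq_along(subjects)) {
    for (ci in seq_len(k)) {
      row <- which(erps$subject == subjects[si] & erps$cell == cell_order[ci])
      if (length(row) != 1) {
        rlang::abort(sprintf("subject %s must contribute exactly one map for cell %s",
                             subjects[si], cell_order[ci]))
      }
      m <- erps$map[[row]]
      if (normalized) m <- normalize_by_gfp(m)
      # channel-fastest within timepoint
      M[(si - 1L) * k + ci, ] <- as.vector(m)
    }
  }
  list(M = M, subjects = subjects, n_ch = n_ch, n_t = n_t)
}

new_tanova_result <- function(effect, times_ms, observed, p, perm_stats,
                              n_perm, seed, alpha, n_subjects, normalized,
                              window_ms = NULL) {
  structure(list(effect = effect, times_ms = times_ms, observed = observed,
                 p = p, perm_stats = perm_stats, n_perm = n_perm, seed = seed,
                 alpha = alpha, n_subjects = n_subjects,
                 normalized = normalized, window_ms = window_ms),
            class = "tanova_result")
}

#' @export
print.tanova_result <- function(x, ...) {
  cat(sprintf("<tanova_result> effect %s: %d timepoints, %d permutations, min p = %.4g, %d timepoints with p < %.2g\n",
              x$effect, length(x$p), x$n_perm, min(x$p), sum(x$p < x$alpha), x$alpha))
  invisible(x)
}

#' Point-by-point topographic ANOVA (TANOVA)
#'
#' At each timepoint the observed statistic is the global dissimilarity
#' index between the grand-mean marginal maps of the tested factor (for the
#' interaction: the RMS across channels of the grand-mean double-difference
#' map). The null distribution is built by randomly reassigning, within
#' each subject, the condition labels of that subject's maps, and the
#' p-value is `(1 + #permutation stats >= observed) / (1 + n_perm)` (ties
#' count as exceedances, and p is never zero).
#'
#' `effect = "between_sets"` tests two paired conditions (e.g. per-category
#' repetition-difference maps), permuting the two labels within subject.
#'
#' @param erps A `condition_erp` tibble; every subject must contribute all
#'   tested cells.
#' @param effect `"repetition_main"`, `"expectation_main"`,
#'   `"interaction"`, or `"between_sets"`.
#' @param n_perm Number of random permutations (default 5000).
#' @param seed Integer seed for the permutation stream.
#' @param normalized Normalize each subject-condition map to unit GFP per
#'   timepoint before testing (pure topography contrast).
#' @param alpha Nominal pointwise significance level stored with the result.
#' @param scheme `"full_cell"` (default) reassigns all four cells uniformly;
#'   `"restricted"` permutes only the tested factor's levels within each
#'   level of the other factor (main effects only).
#' @param sets For `between_sets`: the two cell labels to compare
#'   (defaults to the two distinct cells present).
#' @return A `tanova_result` with per-timepoint observed statistic,
#'   p-values and the permutation statistic matrix.
#' @export
tanova_pointwise <- function(erps, effect = tanova_effects, n_perm = 5000,
                             seed = 1L, normalized = FALSE, alpha = 0.05,
                             scheme = c("full_cell", "restricted"),
                             sets = NULL) {
  effect <- match.arg(effect)
  scheme <- match.arg(scheme)
  if (n_perm < 1) rlang::abort("`n_perm` must be at least 1")
  times <- erp_times(erps)
  if (length(unique(erps$subject)) < 2) rlang::abort("need at least 2 subjects")

  if (effect == "between_sets") {
    cells <- sets %||% unique(erps$cell)
    if (length(cells) != 2) rlang::abort("`between_sets` compares exactly two conditions")
    st <- stack_maps(erps, cells, normalized)
    coef <- rep(c(1, -1), length(st$subjects))
    res <- tanova_engine(st$M, coef, length(st$subjects), 2, st$n_ch, st$n_t,
                         n_perm, seed, scheme = "full_cell")
  } else {
    cells <- c("Exp_Rep", "Unexp_Alt", "Unexp_Rep", "Exp_Alt")
    miss <- setdiff(cells, unique(erps$cell))
    if (length(miss) > 0) {
      rlang::abort(sprintf("missing design cell(s): %s", paste(miss, collapse = ", ")))
    }
    st <- stack_maps(erps, cells, normalized)
    info <- tibble::tibble(cell = cells,
                           is_repetition = grepl("Rep$", cells),
                           is_expected = grepl("^Exp", cells))
    coef1 <- factorial_coef(effect, info)
    coef <- rep(coef1, length(st$subjects))
    strata <- NULL
    if (scheme == "restricted") {
      if (effect == "interaction") {
        rlang::abort("the restricted scheme applies to main effects only")
      }
      other <- if (effect == "repetition_main") info$is_expected else info$is_repetition
      strata <- rep(as.integer(other), length(st$subjects))
    }
    res <- tanova_engine(st$M, coef, length(st$subjects), 4, st$n_ch, st$n_t,
                         n_perm, seed, scheme = scheme, strata = strata)
  }
  new_tanova_result(effect, times, res$observed, res$p, res$perm_stats,
                    n_perm, seed, alpha, length(unique(erps$subject)),
                    normalized)
}

#' Window-averaged topographic permutation test
#'
#' Averages each subject-condition map over the window, then runs a single
#' GDI permutation test on the window-mean maps (used e.g. for topography
#' contrasts between repetition-difference maps, and for early-versus-late
#' interval comparisons). A one-sample window reduces exactly to the
#' pointwise test at that sample.
#'
#' @inheritParams tanova_pointwise
#' @param window_ms Length-2 window over which maps are averaged.
#' @return A `tanova_result` with a single timepoint (the window centre)
#'   and the window stored in `window_ms`.
#' @export
tanova_window <- function(erps, window_ms, effect = tanova_effects,
                          n_perm = 5000, seed = 1L, normalized = FALSE,
                          alpha = 0.05, sets = NULL) {
  effect <- match.arg(effect)
  times <- erp_times(erps)
  idx <- which(times >= window_ms[1] & times <= window_ms[2])
  if (length(idx) == 0) rlang::abort("`window_ms` contains no samples")
  win <- erps
  win$map <- purrr::map(erps$map, function(m) {
    m <- if (normalized) normalize_by_gfp(m[, idx, drop = FALSE]) else m[, idx, drop = FALSE]
    matrix(rowMeans(m), ncol = 1, dimnames = list(rownames(m), NULL))
  })
  win <- new_condition_erp(win, times_ms = mean(times[idx]),
                           montage = erp_montage(erps))
  out <- tanova_pointwise(win, effect, n_perm = n_perm, seed = seed,
                          normalized = FALSE, alpha = alpha, sets = sets)
  out$normalized <- normalized
  out$window_ms <- as.numeric(window_ms)
  out
}

#' Per-subject repetition difference maps
#'
#' Collapses the expectation factor and returns, per subject and category,
#' the repetition-minus-alternation marginal difference map, labelled by
#' category in `cell` so the result feeds directly into `between_sets`
#' contrasts.
#'
#' @param erps A `condition_erp` tibble with the four design cells (and
#'   optionally several categories).
#' @return A `condition_erp` tibble of difference maps.
#' @export
repetition_difference <- function(erps) {
  times <- erp_times(erps)
  montage <- erp_montage(erps)
  tbl <- tibble::as_tibble(erps)
  out <- tbl |>
    dplyr::group_by(.data$subject, .data$category, .data$is_repetition) |>
    dplyr::summarise(map = list(Reduce(`+`, .data$map) / dplyr::n()),
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "is_repetition", values_from = "map",
                       names_prefix = "rep_") |>
    dplyr::mutate(map = purrr::map2(.data$rep_TRUE, .data$rep_FALSE, `-`),
                  cell = ifelse(is.na(.data$category), "difference", .data$category),
                  is_repetition = NA, is_expected = NA, n_trials = NA_integer_) |>
    dplyr::select("subject", "category", "cell", "is_repetition",
                  "is_expected", "n_trials", "map")
  new_condition_erp(out, times, montage)
}
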