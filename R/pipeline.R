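#' Analysis configuration
#'
#' Collects the tuning knobs of the full analysis: permutation count,
#' pointwise alpha, GDS percentile, the analysed interval (defaults to the
#' whole epoch), GFP-normalization flags and the seed.
#'
#' @param n_perm Permutations per test (default 5000; calibrated runs should
#'   use at least 100).
#' @param alpha Pointwise significance level.
#' @param gds_percentile Percentile for the duration threshold.
#' @param analysis_window_ms Optional `[from, to]` restriction of the tested
#'   interval; `NULL` analyses every sample.
#' @param normalized Run the factorial TANOVAs on GFP-normalized maps
#'   (default FALSE: raw maps for the factorial tests, normalization only in
#'   dedicated topography contrasts).
#' @param seed Integer seed for every permutation stream.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(n_perm = 5000, alpha = 0.05, gds_percentile = 95,
                            analysis_window_ms = NULL, normalized = FALSE,
                            seed = 1L) {
  if (n_perm < 1) rlang::abort("`n_perm` must be positive")
  if (n_perm < 100) rlang::warn("fewer than 100 permutations gives a very coarse p-value grid")
  if (alpha <= 0 || alpha >= 1) rlang::abort("`alpha` must lie in (0, 1)")
  structure(list(n_perm = as.integer(n_perm), alpha = alpha,
                 gds_percentile = gds_percentile,
                 analysis_window_ms = analysis_window_ms,
                 normalized = isTRUE(normalized), seed = as.integer(seed)),
            class = "analysis_config")
}

restrict_window <- function(erps, window_ms) {
  if (is.null(window_ms)) return(erps)
  times <- erp_times(erps)
  idx <- which(times >= window_ms[1] & times <= window_ms[2])
  if (length(idx) == 0) rlang::abort("`analysis_window_ms` contains no samples")
  out <- erps
  out$map <- purrr::map(erps$map, function(m) m[, idx, drop = FALSE])
  new_condition_erp(out, times[idx], erp_montage(erps))
}

# effect sizes for the surviving windows of one corrected test
window_effect_sizes <- function(erps, effect, gds, result, sets = NULL,
                                normalized = FALSE) {
  surv <- gds$runs[gds$runs$surviving, , drop = FALSE]
  if (nrow(surv) == 0) {
    return(tibble::tibble(effect = character(), onset_ms = numeric(),
                          offset_ms = numeric(), partial_eta2 = numeric(),
                          cohen_d = numeric(), z_score = numeric(),
                          cohen_d_permutation = numeric()))
  }
  purrr::map_dfr(seq_len(nrow(surv)), function(i) {
    w <- c(surv$onset_ms[i], surv$offset_ms[i])
    eta2 <- effect_size_eta2(erps, effect, w, normalized = normalized, sets = sets)
    zd <- cohens_d_permutation(result, w)
    # eta2 == 1 only in the degenerate zero-residual limit; report d as Inf
    d <- if (eta2 < 1) eta2_to_cohens_d(eta2) else Inf
    tibble::tibble(effect = gds$effect, onset_ms = w[1], offset_ms = w[2],
                   partial_eta2 = eta2, cohen_d = d,
                   z_score = zd$z_score, cohen_d_permutation = zd$cohen_d)
  })
}

#' Factorial (repetition x expectation) analysis of one category
#'
#' Runs the pointwise TANOVA for the repetition and expectation main
#' effects and their interaction, corrects each with global duration
#' statistics, and computes effect sizes over every surviving window.
#'
#' @param erps A `condition_erp` tibble with the four design cells per
#'   subject.
#' @param category Optional category label to filter on first.
#' @param config An [analysis_config()].
#' @return A `factorial_analysis` list: `tanova` and `gds` (named per
#'   effect), a `windows` tibble of all runs, and an `effect_sizes` tibble
#'   for surviving windows.
#' @export
run_factorial_analysis <- function(erps, category = NULL,
                                   config = analysis_config()) {
  if (!is.null(category)) {
    keep <- !is.na(erps$category) & erps$category == category
    erps <- new_condition_erp(erps[keep, ], erp_times(erps), erp_montage(erps))
    if (nrow(erps) == 0) rlang::abort(sprintf("no maps for category '%s'", category))
  }
  erps <- restrict_window(erps, config$analysis_window_ms)
  effects <- c("repetition_main", "expectation_main", "interaction")
  tanova <- list(); gds <- list(); windows <- list(); sizes <- list()
  for (e in effects) {
    res <- tanova_pointwise(erps, e, n_perm = config$n_perm,
                            seed = config$seed, alpha = config$alpha,
                            normalized = config$normalized)
    g <- apply_gds(res, alpha = config$alpha, percentile = config$gds_percentile)
    tanova[[e]] <- res
    gds[[e]] <- g
    w <- g$runs
    if (nrow(w) > 0) w$effect <- e
    windows[[e]] <- w
    sizes[[e]] <- window_effect_sizes(erps, e, g, res,
                                      normalized = config$normalized)
  }
  structure(list(category = category, tanova = tanova, gds = gds,
                 windows = dplyr::bind_rows(windows),
                 effect_sizes = dplyr::bind_rows(sizes),
                 config = config),
            class = "factorial_analysis")
}

#' @export
print.factorial_analysis <- function(x, ...) {
  cat(sprintf("<factorial_analysis>%s: %d run(s), %d surviving window(s)\n",
              if (is.null(x$category)) "" else paste0(" category ", x$category),
              nrow(x$windows), sum(x$windows$surviving %||% FALSE)))
  if (nrow(x$effect_sizes) > 0) print(x$effect_sizes)
  invisible(x)
}

# dispersion TANOVA across K paired conditions: statistic is the RMS (over
# channels and levels) of the level grand means around the overall grand
# mean; null built by permuting level labels within subject.
tanova_levels_dispersion <- function(erps, n_perm = 5000, seed = 1L,
                                     alpha = 0.05, normalized = FALSE) {
  times <- erp_times(erps)
  levels <- sort(unique(erps$cell))
  k <- length(levels)
  if (k < 2) rlang::abort("need at least two conditions")
  st <- stack_maps(erps, levels, normalized)
  S <- length(st$subjects)
  n_ch <- st$n_ch; n_t <- st$n_t
  rms_by_time <- function(sq_sum) { # sq_sum: n x (ch*t) accumulated squares
    out <- matrix(0, nrow(sq_sum), n_t)
    for (c in seq_len(n_ch)) {
      out <- out + sq_sum[, (seq_len(n_t) - 1L) * n_ch + c, drop = FALSE]
    }
    sqrt(out / (n_ch * k))
  }
  grand <- colMeans(st$M)
  level_means <- function(assign) {
    # assign: S x k matrix, assign[s, j] = level slot of subject s's j-th map
    G2 <- matrix(0, 1, n_ch * n_t)
    for (lev in seq_len(k)) {
      coef <- as.numeric(t(assign == lev)) / S
      G2 <- G2 + (crossprod(st$M, coef)[, 1] - grand)^2
    }
    G2
  }
  obs_assign <- matrix(rep(seq_len(k), S), S, k, byrow = TRUE)
  observed <- drop(rms_by_time(matrix(level_means(obs_assign), 1)))

  all_perms <- perms_of(k)
  perm_stats <- matrix(NA_real_, n_perm, n_t)
  withr_seed(seed, {
    for (b in seq_len(n_perm)) {
      assign <- all_perms[sample.int(nrow(all_perms), S, replace = TRUE), , drop = FALSE]
      perm_stats[b, ] <- rms_by_time(matrix(level_means(assign), 1))
    }
  })
  p <- (1 + colSums(perm_stats >= matrix(observed, n_perm, n_t, byrow = TRUE))) /
    (1 + n_perm)
  new_tanova_result("levels_dispersion", times, observed, p, perm_stats,
                    n_perm, seed, alpha, S, normalized)
}

#' Cross-category repetition-effect analysis
#'
#' Reduces each subject's data to per-category repetition-difference maps,
#' then (1) tests the repetition x category interaction pointwise (a
#' dispersion TANOVA over the category level means) with GDS correction,
#' (2) runs the three pairwise repetition-effect contrasts pointwise, each
#' GDS-corrected with effect sizes over surviving windows, (3) optionally
#' compares window-mean difference-map topographies between category pairs
#' on GFP-normalized maps (each category averaged over its own component
#' window), and (4) optionally contrasts an early versus a late interval of
#' one category's difference maps on normalized topographies.
#'
#' @param erps A `condition_erp` tibble with all four cells for at least
#'   two categories per subject.
#' @param config An [analysis_config()].
#' @param topography_windows Named list mapping category to its `[on, off]`
#'   component window for the normalized topography contrasts (optional).
#' @param interval_split Optional list with elements `category`, `early`,
#'   `late` for the early-versus-late topography comparison.
#' @return A `cross_category_analysis` list.
#' @export
run_cross_category_analysis <- function(erps, config = analysis_config(),
                                        topography_windows = NULL,
                                        interval_split = NULL) {
  cats <- sort(unique(erps$category[!is.na(erps$category)]))
  if (length(cats) < 2) {
    rlang::abort("cross-category analysis needs at least two categories")
  }
  erps <- restrict_window(erps, config$analysis_window_ms)
  diffs <- repetition_difference(erps)

  interaction <- tanova_levels_dispersion(diffs, n_perm = config$n_perm,
                                          seed = config$seed,
                                          alpha = config$alpha)
  interaction_gds <- apply_gds(interaction, alpha = config$alpha,
                               percentile = config$gds_percentile)

  pairs <- utils::combn(cats, 2, simplify = FALSE)
  pairwise <- purrr::map(pairs, function(pr) {
    sub <- diffs[diffs$cell %in% pr, ]
    sub <- new_condition_erp(sub, erp_times(diffs), erp_montage(diffs))
    res <- tanova_pointwise(sub, "between_sets", n_perm = config$n_perm,
                            seed = config$seed, alpha = config$alpha,
                            sets = pr)
    g <- apply_gds(res, alpha = config$alpha, percentile = config$gds_percentile)
    sizes <- window_effect_sizes(sub, "between_sets", g, res, sets = pr)
    list(pair = pr, tanova = res, gds = g, effect_sizes = sizes)
  })
  names(pairwise) <- purrr::map_chr(pairs, paste, collapse = "_vs_")

  topo <- NULL
  if (!is.null(topography_windows)) {
    topo <- purrr::map(pairs, function(pr) {
      sub <- purrr::map_dfr(pr, function(cat) {
        rows <- diffs[diffs$cell == cat, ]
        idx <- {
          w <- topography_windows[[cat]]
          times <- erp_times(diffs)
          which(times >= w[1] & times <= w[2])
        }
        rows$map <- purrr::map(rows$map, function(m) {
          matrix(rowMeans(m[, idx, drop = FALSE]), ncol = 1,
                 dimnames = list(rownames(m), NULL))
        })
        rows
      })
      sub <- new_condition_erp(sub, 0, erp_montage(diffs))
      res <- tanova_pointwise(sub, "between_sets", n_perm = config$n_perm,
                              seed = config$seed, alpha = config$alpha,
                              normalized = TRUE, sets = pr)
      eta2 <- effect_size_eta2(sub, "between_sets", c(-Inf, Inf),
                               normalized = TRUE, sets = pr)
      tibble::tibble(pair = paste(pr, collapse = "_vs_"), p_value = res$p,
                     partial_eta2 = eta2, cohen_d = eta2_to_cohens_d(eta2))
    })
    topo <- dplyr::bind_rows(topo)
  }

  split <- NULL
  if (!is.null(interval_split)) {
    split <- compare_interval_topography(diffs, interval_split$category,
                                         interval_split$early,
                                         interval_split$late,
                                         n_perm = config$n_perm,
                                         seed = config$seed,
                                         alpha = config$alpha)
  }

  structure(list(categories = cats, interaction = interaction,
                 interaction_gds = interaction_gds, pairwise = pairwise,
                 topography = topo, interval_split = split, config = config),
            class = "cross_category_analysis")
}

#' Compare the topography of two intervals of a difference map
#'
#' Averages one category's repetition-difference maps over an early and a
#' late window, normalizes each window-mean map to unit GFP, and runs a
#' paired two-condition permutation test between the two interval
#' topographies.
#'
#' @param diffs Difference maps from [repetition_difference()].
#' @param category Category to analyse (`NULL` if `diffs` has one set).
#' @param early,late The two `[on, off]` windows in ms.
#' @param n_perm,seed,alpha As in [tanova_pointwise()].
#' @return A tibble with `p_value`, `partial_eta2` and `cohen_d`.
#' @export
compare_interval_topography <- function(diffs, category = NULL, early, late,
                                        n_perm = 5000, seed = 1L,
                                        alpha = 0.05) {
  rows <- if (is.null(category)) diffs else diffs[diffs$cell == category, ]
  if (nrow(rows) == 0) rlang::abort("no difference maps for this category")
  times <- erp_times(diffs)
  win_mean <- function(m, w) {
    idx <- which(times >= w[1] & times <= w[2])
    matrix(rowMeans(m[, idx, drop = FALSE]), ncol = 1,
           dimnames = list(rownames(m), NULL))
  }
  both <- dplyr::bind_rows(
    dplyr::mutate(rows, cell = "early", map = purrr::map(.data$map, win_mean, early)),
    dplyr::mutate(rows, cell = "late", map = purrr::map(.data$map, win_mean, late))
  )
  both <- new_condition_erp(both, 0, erp_montage(diffs))
  res <- tanova_pointwise(both, "between_sets", n_perm = n_perm, seed = seed,
                          alpha = alpha, normalized = TRUE,
                          sets = c("early", "late"))
  eta2 <- effect_size_eta2(both, "between_sets", c(-Inf, Inf),
                           normalized = TRUE, sets = c("early", "late"))
  tibble::tibble(p_value = res$p, partial_eta2 = eta2,
                 cohen_d = eta2_to_cohens_d(eta2))
}

#' @export
print.cross_category_analysis <- function(x, ...) {
  cat(sprintf("<cross_category_analysis> categories: %s\n",
              paste(x$categories, collapse = ", ")))
  surv <- x$interaction_gds$runs[x$interaction_gds$runs$surviving, , drop = FALSE]
  cat(sprintf("  repetition x category interaction: %d surviving window(s)\n", nrow(surv)))
  for (nm in names(x$pairwise)) {
    s <- x$pairwise[[nm]]$gds$runs
    cat(sprintf("  %s: %d surviving window(s)\n", nm, sum(s$surviving)))
  }
  invisible(x)
}
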