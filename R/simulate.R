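#' Build a zero-mean, unit-GFP scalp topography
#'
#' Places Gaussian bumps (in montage distance units) on the requested focus
#' channels, optionally signed, then re-centres the map to zero mean across
#' channels (average-reference construction) and scales it to unit global
#' field power. Such templates are the spatial patterns injected by the
#' simulator.
#'
#' @param montage A montage tibble (see [make_montage()]).
#' @param focus_channels Channel labels at bump centres.
#' @param spatial_sigma Gaussian bump width in montage units.
#' @param signs Bump polarities, recycled along `focus_channels`.
#' @return Named numeric vector over channels with `mean == 0` and
#'   `gfp() == 1`.
#' @examples
#' m <- make_montage(32)
#' topo <- make_topography(m, c("PO7", "PO8"), 0.4, signs = c(-1, -1))
#' gfp(topo)
#' @export
make_topography <- function(montage, focus_channels, spatial_sigma = 0.5,
                            signs = 1) {
  montage <- validate_montage(montage)
  missing <- setdiff(focus_channels, montage$channel)
  if (length(missing) > 0) {
    rlang::abort(sprintf("unknown channel label(s): %s", paste(missing, collapse = ", ")))
  }
  signs <- rep_len(signs, length(focus_channels))
  d <- montage_distances(montage)
  map <- rep(0, nrow(montage))
  for (k in seq_along(focus_channels)) {
    map <- map + signs[k] * exp(-d[, focus_channels[k]]^2 / (2 * spatial_sigma^2))
  }
  map <- map - mean(map)
  g <- gfp(map)
  if (g < 1e-12) {
    rlang::abort("degenerate topography: map is flat after average-reference centring")
  }
  stats::setNames(map / g, montage$channel)
}

#' Specify an injectable condition effect
#'
#' An effect is a fixed scalp topography modulated by a temporal envelope
#' inside a latency window and signed per trial according to the tested
#' contrast. Contrast coding is balanced so that `amplitude` equals the
#' magnitude of the induced condition-difference map at the envelope peak:
#' `repetition_main` adds +/- amplitude/2 by repetition status,
#' `expectation_main` +/- amplitude/2 by expectation status, `interaction`
#' +/- amplitude/4 with the product sign (double difference equals
#' `amplitude`), and `category_specific` applies the repetition contrast
#' only within the named category.
#'
#' @param name Effect label for reports.
#' @param contrast One of `"repetition_main"`, `"expectation_main"`,
#'   `"interaction"`, `"category_specific"`.
#' @param topography Zero-mean, unit-GFP named channel vector
#'   (see [make_topography()]).
#' @param window_ms Length-2 onset/offset of the effect in ms.
#' @param amplitude Peak condition-difference amplitude in microvolts.
#' @param category Category label, required for `category_specific`.
#' @param envelope `"raised_cosine"` (default) or `"boxcar"`.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(name, contrast, topography, window_ms, amplitude,
                        category = NULL,
                        envelope = c("raised_cosine", "boxcar")) {
  contrast <- match.arg(contrast, c("repetition_main", "expectation_main",
                                    "interaction", "category_specific"))
  envelope <- match.arg(envelope)
  if (length(window_ms) != 2 || diff(window_ms) <= 0) {
    rlang::abort("`window_ms` must be an increasing [onset, offset] pair")
  }
  if (abs(mean(topography)) > 1e-6) {
    rlang::abort("`topography` must have zero mean across channels")
  }
  if (abs(gfp(topography) - 1) > 1e-6) {
    rlang::abort("`topography` must have unit global field power")
  }
  if (contrast == "category_specific" && is.null(category)) {
    rlang::abort("`category` is required for a category_specific effect")
  }
  structure(list(name = name, contrast = contrast, topography = topography,
                 window_ms = as.numeric(window_ms), amplitude = amplitude,
                 category = category, envelope = envelope),
            class = "effect_spec")
}

#' Specify the noise model
#'
#' Single-trial noise is white Gaussian per channel, filtered to a
#' stationary AR(1) process along time, then mixed across channels by the
#' symmetric square root of a distance-based Gaussian kernel, so that each
#' channel keeps marginal standard deviation `trial_noise_sd` while the
#' noise is temporally autocorrelated and spatially smooth. Per-subject
#' effect amplitudes are scaled by a lognormal factor with median 1.
#'
#' @param trial_noise_sd Per-channel, per-sample noise SD in microvolts.
#' @param spatial_smoothing_sigma Kernel length scale in montage units.
#' @param ar1_coefficient Lag-1 autocorrelation, in (-1, 1).
#' @param subject_amplitude_sd Lognormal sigma of per-subject effect scaling.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(trial_noise_sd = 20,
                       spatial_smoothing_sigma = 0.6,
                       ar1_coefficient = 0.7,
                       subject_amplitude_sd = 0.3) {
  if (trial_noise_sd < 0) rlang::abort("`trial_noise_sd` must be >= 0")
  if (abs(ar1_coefficient) >= 1) rlang::abort("`ar1_coefficient` must lie in (-1, 1)")
  if (subject_amplitude_sd < 0) rlang::abort("`subject_amplitude_sd` must be >= 0")
  structure(list(trial_noise_sd = trial_noise_sd,
                 spatial_smoothing_sigma = spatial_smoothing_sigma,
                 ar1_coefficient = ar1_coefficient,
                 subject_amplitude_sd = subject_amplitude_sd),
            class = "noise_spec")
}

# Gaussian spatial kernel (unit diagonal) and its symmetric PSD square root
spatial_kernel <- function(montage, sigma) {
  d <- montage_distances(montage)
  exp(-d^2 / (2 * sigma^2))
}

spatial_kernel_sqrt <- function(montage, sigma) {
  K <- spatial_kernel(montage, sigma)
  e <- eigen(K, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

# stationary AR(1) noise, dim (n_time, n_series), unit marginal variance
ar1_noise <- function(n_time, n_series, phi) {
  e <- matrix(stats::rnorm(n_time * n_series), n_time, n_series)
  if (phi != 0 && n_time > 1) {
    e[-1, ] <- e[-1, , drop = FALSE] * sqrt(1 - phi^2)
    for (t in 2:n_time) e[t, ] <- e[t, ] + phi * e[t - 1, ]
  }
  e
}

raised_cosine <- function(times_ms, window_ms) {
  u <- (times_ms - window_ms[1]) / diff(window_ms)
  ifelse(u >= 0 & u <= 1, 0.5 * (1 - cos(2 * pi * u)), 0)
}

boxcar <- function(times_ms, window_ms) {
  as.numeric(times_ms >= window_ms[1] & times_ms <= window_ms[2])
}

effect_envelope <- function(effect, times_ms) {
  switch(effect$envelope,
         raised_cosine = raised_cosine(times_ms, effect$window_ms),
         boxcar = boxcar(times_ms, effect$window_ms))
}

# per-trial signed coefficient implementing the contrast coding
effect_trial_coef <- function(effect, trials) {
  s_rep <- 2 * trials$is_repetition - 1
  s_exp <- 2 * trials$is_expected - 1
  switch(effect$contrast,
    repetition_main  = s_rep / 2,
    expectation_main = s_exp / 2,
    interaction      = s_rep * s_exp / 4,
    category_specific = (trials$category == effect$category) * s_rep / 2
  )
}

epoch_times <- function(epoch_window_ms, sampling_rate) {
  seq(epoch_window_ms[1], epoch_window_ms[2], by = 1000 / sampling_rate)
}

new_erp_epochs <- function(data, times_ms, sampling_rate, montage,
                           trial_table, subject_id = NA_character_,
                           seed = NA_integer_) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[2] == nrow(montage),
            dim(data)[3] == length(times_ms),
            dim(data)[1] == nrow(trial_table))
  structure(list(data = data, times_ms = times_ms,
                 sampling_rate = sampling_rate, montage = montage,
                 trial_table = trial_table, subject_id = subject_id,
                 seed = seed),
            class = "erp_epochs")
}

#' @export
print.erp_epochs <- function(x, ...) {
  cat(sprintf("<erp_epochs> subject %s: %d trials x %d channels x %d samples (%g Hz, %g..%g ms)\n",
              x$subject_id, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$sampling_rate, min(x$times_ms), max(x$times_ms)))
  invisible(x)
}

#' Simulate single-trial epochs for one subject
#'
#' Forward model: each trial's signal is the sum over applicable effects of
#' `amplitude * subject_scale * envelope(t) * topography * contrast sign`,
#' plus noise that is AR(1) along time and spatially correlated across
#' channels (see [noise_spec()]). The expectation of the condition-mean
#' difference map therefore equals the injected contrast exactly.
#'
#' @param trials A trial table (see [build_category_trials()]).
#' @param effects List of [effect_spec()] objects (possibly empty).
#' @param noise A [noise_spec()].
#' @param montage A montage tibble.
#' @param sampling_rate Sampling rate in Hz (default 250).
#' @param epoch_window_ms Epoch limits relative to S2 onset (default
#'   `c(-150, 850)`).
#' @param seed Integer seed.
#' @param subject_scale Multiplicative effect scaling for this subject.
#' @param subject_id Identifier stored with the data.
#' @return An `erp_epochs` object: `data` (trials x channels x time, uV)
#'   plus times, montage and the trial table.
#' @export
simulate_subject_epochs <- function(trials, effects = list(), noise = noise_spec(),
                                    montage = make_montage(),
                                    sampling_rate = 250,
                                    epoch_window_ms = c(-150, 850),
                                    seed = 1L, subject_scale = 1,
                                    subject_id = "s01") {
  stopifnot(inherits(noise, "noise_spec"))
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  times <- epoch_times(epoch_window_ms, sampling_rate)
  n_ch <- nrow(montage)
  n_t <- length(times)
  n_trials <- nrow(trials)
  for (e in effects) {
    if (e$window_ms[1] < epoch_window_ms[1] || e$window_ms[2] > epoch_window_ms[2]) {
      rlang::abort(sprintf("effect '%s' window lies outside the epoch", e$name))
    }
    if (!identical(names(e$topography), montage$channel)) {
      rlang::abort(sprintf("effect '%s' topography channels do not match the montage", e$name))
    }
  }

  data <- array(0, dim = c(n_trials, n_ch, n_t))
  for (e in effects) {
    coef <- effect_trial_coef(e, trials) * e$amplitude * subject_scale
    pattern <- outer(unname(e$topography), effect_envelope(e, times)) # ch x t
    nz <- which(coef != 0)
    for (i in nz) data[i, , ] <- data[i, , ] + coef[i] * pattern
  }

  if (noise$trial_noise_sd > 0) {
    withr_seed(seed, {
      Ks <- spatial_kernel_sqrt(montage, noise$spatial_smoothing_sigma)
      e <- ar1_noise(n_t, n_ch * n_trials, noise$ar1_coefficient)
      dim(e) <- c(n_t, n_ch, n_trials)
      for (i in seq_len(n_trials)) {
        data[i, , ] <- data[i, , ] + noise$trial_noise_sd * t(e[, , i] %*% Ks)
      }
    })
  }
  dimnames(data) <- list(NULL, montage$channel, NULL)
  new_erp_epochs(data, times, sampling_rate, montage, trials,
                 subject_id = subject_id, seed = seed)
}

#' Simulate a multi-subject study
#'
#' Derives independent per-subject seeds deterministically from the master
#' seed, draws one lognormal effect-scaling factor per subject (median 1),
#' builds each subject's randomized trial sequence, and simulates epochs.
#'
#' @param n_subjects Number of subjects (>= 2; default 33).
#' @param spec A [design_spec()].
#' @inheritParams simulate_subject_epochs
#' @param seed Master seed.
#' @return A list of `erp_epochs`, one per subject.
#' @export
simulate_study <- function(n_subjects = 33, spec = design_spec(),
                           effects = list(), noise = noise_spec(),
                           montage = make_montage(), sampling_rate = 250,
                           epoch_window_ms = c(-150, 850), seed = 1L) {
  if (n_subjects < 2) rlang::abort("`n_subjects` must be at least 2")
  draws <- withr_seed(seed, list(
    seeds = sample.int(2^31 - 1, n_subjects),
    scales = exp(stats::rnorm(n_subjects, 0, noise$subject_amplitude_sd))
  ))
  purrr::map(seq_len(n_subjects), function(s) {
    sp <- spec
    sp$seed <- draws$seeds[s]
    trials <- build_full_design(sp)
    simulate_subject_epochs(trials, effects, noise, montage, sampling_rate,
                            epoch_window_ms, seed = draws$seeds[s] %% 2^30 + s,
                            subject_scale = draws$scales[s],
                            subject_id = sprintf("s%02d", s))
  })
}

#' Simulate subject-by-condition ERP maps directly
#'
#' ERP-level shortcut for calibration studies: instead of simulating and
#' averaging single trials, each subject x cell average map is drawn as
#' injected effect signal plus residual noise whose SD (`erp_noise_sd`)
#' represents the noise remaining in a trial-averaged ERP. Noise is AR(1)
#' along time and spatially correlated, as in [simulate_subject_epochs()].
#' With no effects this generates the global null used for false-positive
#' calibration.
#'
#' @param n_subjects Number of subjects.
#' @param effects List of [effect_spec()] objects.
#' @param erp_noise_sd Residual noise SD of an averaged ERP, in microvolts.
#' @param noise A [noise_spec()] supplying the spatial/temporal correlation
#'   parameters and the subject scaling SD.
#' @param montage Montage tibble.
#' @param n_timepoints Number of samples in the epoch.
#' @param epoch_window_ms Epoch limits in ms.
#' @param cells Condition cells each subject contributes.
#' @param categories Optional category label(s) recycled over cells.
#' @param seed Integer seed.
#' @return A `condition_erp` tibble: one row per subject x cell with a
#'   channels x time `map` list-column.
#' @export
simulate_condition_erps <- function(n_subjects = 20, effects = list(),
                                    erp_noise_sd = 1, noise = noise_spec(),
                                    montage = make_montage(32),
                                    n_timepoints = 250,
                                    epoch_window_ms = c(-150, 850),
                                    cells = c("Exp_Rep", "Exp_Alt",
                                              "Unexp_Rep", "Unexp_Alt"),
                                    categories = NULL,
                                    seed = 1L) {
  if (n_subjects < 2) rlang::abort("`n_subjects` must be at least 2")
  if (inherits(effects, "effect_spec")) effects <- list(effects)
  times <- seq(epoch_window_ms[1], epoch_window_ms[2], length.out = n_timepoints)
  n_ch <- nrow(montage)
  cell_tab <- tibble::tibble(
    cell = cells,
    category = if (is.null(categories)) NA_character_ else rep_len(categories, length(cells))
  )
  cell_tab$is_repetition <- grepl("Rep$", cell_tab$cell)
  cell_tab$is_expected <- grepl("^Exp", cell_tab$cell)

  withr_seed(seed, {
    Ks <- if (erp_noise_sd > 0) spatial_kernel_sqrt(montage, noise$spatial_smoothing_sigma)
    scales <- exp(stats::rnorm(n_subjects, 0, noise$subject_amplitude_sd))
    rows <- purrr::map(seq_len(n_subjects), function(s) {
      maps <- purrr::map(seq_len(nrow(cell_tab)), function(k) {
        m <- matrix(0, n_ch, n_timepoints,
                    dimnames = list(montage$channel, NULL))
        for (e in effects) {
          coef <- effect_trial_coef(e, cell_tab[k, ]) * e$amplitude * scales[s]
          if (coef != 0) {
            m <- m + coef * outer(unname(e$topography), effect_envelope(e, times))
          }
        }
        if (erp_noise_sd > 0) {
          m <- m + erp_noise_sd *
            t(ar1_noise(n_timepoints, n_ch, noise$ar1_coefficient) %*% Ks)
        }
        m
      })
      dplyr::mutate(cell_tab,
                    subject = sprintf("s%02d", s),
                    n_trials = NA_integer_,
                    map = maps)
    })
    erps <- dplyr::bind_rows(rows)
    erps <- erps[, c("subject", "category", "cell", "is_repetition",
                     "is_expected", "n_trials", "map")]
    new_condition_erp(erps, times_ms = times, montage = montage)
  })
}
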