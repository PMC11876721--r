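test_that("built-in montages have unique labels and positions on the unit disc", {
  for (n in c(64, 32)) {
    m <- make_montage(n)
    expect_equal(nrow(m), n)
    expect_equal(anyDuplicated(m$channel), 0)
    expect_true(all(m$x^2 + m$y^2 <= 1 + 1e-12))
  }
  expect_error(make_montage(17), "must be 64 or 32")
})

test_that("topographies are zero-mean with unit GFP", {
  m <- make_montage()
  for (sigma in c(0.2, 0.5, 1)) {
    topo <- make_topography(m, c("PO7", "Cz", "F4"), sigma, signs = c(-1, 1, 1))
    expect_lt(abs(mean(topo)), 1e-12)
    expect_equal(gfp(topo), 1, tolerance = 1e-9)
  }
  expect_error(make_topography(m, "NoSuch", 0.5), "unknown channel")
})

test_that("antisymmetric narrow bumps reduce to a two-point dipole", {
  # oracle: brute-force evaluation of the Gaussian construction on 2 channels
  m <- tiny_montage()
  topo <- make_topography(m, c("L", "R"), spatial_sigma = 1e-4, signs = c(1, -1))
  expect_equal(unname(topo), c(1, -1), tolerance = 1e-9)
})

test_that("noise-free forward model reproduces the injected contrast exactly", {
  m <- make_montage(32)
  topo <- make_topography(m, c("PO7", "PO8"), 0.4, signs = c(-1, -1))
  eff <- effect_spec("rs", "repetition_main", topo, c(200, 300), amplitude = 2)
  spec <- design_spec(categories = "word", trials_per_category = 16,
                      n_stimuli_per_subcategory = 10)
  tr <- build_category_trials(spec, "word")
  ep <- simulate_subject_epochs(tr, list(eff), noise_spec(trial_noise_sd = 0),
                                m, sampling_rate = 100, seed = 2)
  erp <- average_conditions(ep)
  ic <- which.min(abs(erp_times(erp) - 250)) # envelope peak
  rep_map <- (erp$map[[which(erp$cell == "Exp_Rep")]][, ic] +
                erp$map[[which(erp$cell == "Unexp_Rep")]][, ic]) / 2
  alt_map <- (erp$map[[which(erp$cell == "Exp_Alt")]][, ic] +
                erp$map[[which(erp$cell == "Unexp_Alt")]][, ic]) / 2
  expect_equal(unname(rep_map - alt_map), unname(2 * topo), tolerance = 1e-12)

  # linearity: doubling amplitudes doubles the noise-free difference maps
  eff2 <- effect_spec("rs", "repetition_main", topo, c(200, 300), amplitude = 4)
  ep2 <- simulate_subject_epochs(tr, list(eff2), noise_spec(trial_noise_sd = 0),
                                 m, sampling_rate = 100, seed = 2)
  expect_equal(ep2$data, 2 * ep$data, tolerance = 1e-12)
})

test_that("interaction effects produce the stated double difference", {
  m <- small_montage()
  topo <- make_topography(m, "ch01", 0.3)
  eff <- effect_spec("int", "interaction", topo, c(100, 200), amplitude = 3)
  spec <- design_spec(categories = "x", trials_per_category = 8,
                      n_stimuli_per_subcategory = 10)
  tr <- build_category_trials(spec, "x")
  ep <- simulate_subject_epochs(tr, eff, noise_spec(trial_noise_sd = 0), m,
                                sampling_rate = 100, seed = 1)
  erp <- average_conditions(ep)
  ic <- which.min(abs(erp_times(erp) - 150))
  g <- function(cell) erp$map[[which(erp$cell == cell)]][, ic]
  dd <- (g("Exp_Rep") - g("Unexp_Rep")) - (g("Exp_Alt") - g("Unexp_Alt"))
  expect_equal(unname(dd), unname(3 * topo), tolerance = 1e-12)
})

test_that("AR(1) noise has the requested lag-1 autocorrelation", {
  # closed form: stationary AR(1) autocorrelation at lag 1 equals phi
  m <- tiny_montage()
  spec <- design_spec(categories = "x", trials_per_category = 280,
                      n_stimuli_per_subcategory = 20)
  tr <- build_category_trials(spec, "x")
  ns <- noise_spec(trial_noise_sd = 1, ar1_coefficient = 0.5,
                   spatial_smoothing_sigma = 0.01)
  ep <- simulate_subject_epochs(tr, list(), ns, m, sampling_rate = 250, seed = 4)
  base_idx <- which(ep$times_ms < 0)
  x <- ep$data[, 1, base_idx] # trials x baseline samples, one channel (>10k samples)
  # pooled lag-1 product-moment estimate (the per-trial estimator is biased
  # downward on short segments)
  r1 <- mean(x[, -1] * x[, -ncol(x)]) / mean(x^2)
  expect_equal(r1, 0.5, tolerance = 0.05)
  # marginal scale close to the requested SD
  expect_equal(stats::sd(as.vector(x)), 1, tolerance = 0.05)
})

test_that("noise spatial covariance is PSD and decays with electrode distance", {
  m <- make_montage(32)
  K <- erptopo:::spatial_kernel(m, 0.6)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
  d <- erptopo:::montage_distances(m)
  expect_true(all(K[d > 1.5] < K[2, 1])) # far pairs weaker than a close pair
  # empirical channel covariance approaches the kernel
  set.seed(5)
  Ks <- erptopo:::spatial_kernel_sqrt(m, 0.6)
  e <- matrix(rnorm(20000 * 32), 20000, 32) %*% Ks
  emp <- stats::cov(e)
  expect_equal(emp, K, tolerance = 0.1, ignore_attr = TRUE)
})

test_that("study simulation is reproducible and refuses n_subjects < 2", {
  spec <- design_spec(categories = "x", trials_per_category = 8,
                      n_stimuli_per_subcategory = 10)
  m <- small_montage()
  a <- simulate_study(3, spec, montage = m, sampling_rate = 50, seed = 11)
  b <- simulate_study(3, spec, montage = m, sampling_rate = 50, seed = 11)
  expect_identical(a, b)
  c2 <- simulate_study(3, spec, montage = m, sampling_rate = 50, seed = 12)
  expect_false(identical(a[[1]]$data, c2[[1]]$data))
  expect_error(simulate_study(1, spec, montage = m), "at least 2")
})

test_that("grand-average GDI recovers the injected amplitude", {
  # oracle: the GDI of a zero-mean unit-GFP map scaled by a equals a
  m <- make_montage(32)
  topo <- make_topography(m, c("Cz", "Pz"), 0.5)
  a <- 1.5
  eff <- effect_spec("rs", "repetition_main", topo, c(200, 300), amplitude = a)
  erps <- simulate_condition_erps(n_subjects = 20, effects = list(eff),
                                  erp_noise_sd = 0.1,
                                  noise = noise_spec(subject_amplitude_sd = 0),
                                  montage = m, n_timepoints = 100, seed = 6)
  times <- erp_times(erps)
  ic <- which.min(abs(times - 250))
  grand <- function(cells) {
    maps <- erps$map[erps$cell %in% cells]
    Reduce(`+`, maps)[, ic] / length(maps)
  }
  g <- gdi(grand(c("Exp_Rep", "Unexp_Rep")), grand(c("Exp_Alt", "Unexp_Alt")))
  expect_equal(g, a, tolerance = 0.05)
})

test_that("effect windows outside the epoch and bad AR coefficients error", {
  m <- small_montage()
  topo <- make_topography(m, "ch01", 0.3)
  eff <- effect_spec("late", "repetition_main", topo, c(800, 900), amplitude = 1)
  spec <- design_spec(categories = "x", trials_per_category = 8,
                      n_stimuli_per_subcategory = 10)
  tr <- build_category_trials(spec, "x")
  expect_error(simulate_subject_epochs(tr, eff, noise_spec(), m,
                                       epoch_window_ms = c(-150, 850)),
               "outside the epoch")
  expect_error(noise_spec(ar1_coefficient = 1), "must lie in")
  expect_error(noise_spec(trial_noise_sd = -1), ">= 0")
})
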