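test_that("in-band sinusoids pass through the band-pass filter", {
  fs <- 250
  t <- seq(0, 4, by = 1 / fs)
  mid <- (length(t) %/% 4):(3 * length(t) %/% 4)
  y <- bandpass_filter(sin(2 * pi * 10 * t), sampling_rate = fs)
  expect_equal(max(abs(y[mid])), 1, tolerance = 0.05)
})

test_that("DC input is removed by the high-pass section", {
  fs <- 250
  y <- bandpass_filter(rep(5, 4 * fs), sampling_rate = fs)
  mid <- fs:(3 * fs)
  expect_lt(max(abs(y[mid])), 0.05) # < 1% of the input after edge transients
})

test_that("stop-band attenuation matches the squared Butterworth magnitude", {
  # oracle: zero-phase (forward-backward) 4th-order low-pass at 30 Hz gives
  # |H(f)|^2 = 1 / (1 + (f/30)^8) at f = 50 Hz; bilinear warping is
  # negligible at a 1000 Hz sampling rate
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  y <- bandpass_filter(sin(2 * pi * 50 * t), sampling_rate = fs)
  mid <- (length(t) %/% 4):(3 * length(t) %/% 4)
  expect_equal(max(abs(y[mid])), 1 / (1 + (50 / 30)^8), tolerance = 0.10)
})

test_that("filter input validation works", {
  expect_error(bandpass_filter(rnorm(10), low_hz = 30, high_hz = 0.3,
                               sampling_rate = 250), "invalid band edges")
  expect_error(bandpass_filter(rnorm(10), sampling_rate = 50),
               "twice the upper band edge")
})

test_that("average reference subtracts the channel mean and is idempotent", {
  m <- matrix(c(3, 1), nrow = 2, ncol = 1)
  expect_equal(average_reference(m), matrix(c(1, -1), 2, 1))
  set.seed(1)
  x <- matrix(rnorm(64 * 10), 64, 10)
  once <- average_reference(x)
  expect_equal(average_reference(once), once)
  expect_true(all(abs(colMeans(once)) < 1e-12))
  # GFP unchanged by re-referencing an already average-referenced map
  expect_equal(gfp(average_reference(once)), gfp(once))
})

test_that("baseline correction zeroes the baseline segment and is idempotent", {
  m <- small_montage()
  spec <- design_spec(categories = "x", trials_per_category = 8,
                      n_stimuli_per_subcategory = 10)
  tr <- build_category_trials(spec, "x")
  ep <- simulate_subject_epochs(tr, list(), noise_spec(trial_noise_sd = 5),
                                m, sampling_rate = 100, seed = 3)
  bc <- baseline_correct(ep)
  base_idx <- which(bc$times_ms >= -150 & bc$times_ms <= 0)
  means <- apply(bc$data[, , base_idx], c(1, 2), mean)
  expect_true(all(abs(means) < 1e-12))
  expect_equal(baseline_correct(bc)$data, bc$data, tolerance = 1e-12)

  # constant trials become all-zero
  ep$data[] <- 5
  expect_true(all(baseline_correct(ep)$data == 0))
  expect_error(baseline_correct(bc, window_ms = c(-500, -400)), "no samples")
})

test_that("artifact rejection uses a strict threshold", {
  m <- tiny_montage()
  spec <- design_spec(categories = "x", trials_per_category = 8,
                      n_stimuli_per_subcategory = 10)
  tr <- build_category_trials(spec, "x")
  ep <- simulate_subject_epochs(tr, list(), noise_spec(trial_noise_sd = 0),
                                m, sampling_rate = 50, seed = 1)
  ep$data[1, 1, 5] <- 81   # rejected: exceeds +/- 80
  ep$data[2, 2, 7] <- 80   # kept: exactly at the boundary
  ep$data[3, 1, 2] <- -80.5
  out <- reject_artifacts(ep, threshold_uv = 80)
  expect_equal(which(out$log$rejected), c(1, 3))
  expect_equal(dim(out$epochs$data)[1], 6)
  expect_equal(nrow(out$epochs$trial_table), 6)

  # surviving count matches a brute-force scan on random peaks
  set.seed(9)
  ep2 <- simulate_subject_epochs(tr, list(), noise_spec(trial_noise_sd = 40),
                                 m, sampling_rate = 50, seed = 10)
  res <- reject_artifacts(ep2, 80)
  brute <- sapply(seq_len(8), function(i) max(abs(ep2$data[i, , ])) > 80)
  expect_equal(res$log$rejected, brute)
  expect_equal(dim(res$epochs$data)[1], sum(!brute))
})

test_that("condition averaging matches brute force and drops target trials", {
  m <- small_montage()
  spec <- design_spec(categories = "x", trials_per_category = 20,
                      p_rep_given_highcue = 0.6, p_rep_given_lowcue = 0.4,
                      n_stimuli_per_subcategory = 15)
  tr <- build_category_trials(spec, "x")
  ep <- simulate_subject_epochs(tr, list(), noise_spec(trial_noise_sd = 10),
                                m, sampling_rate = 50, seed = 8)
  erp <- average_conditions(ep)
  for (cl in design_cells) {
    sel <- tr$cell == cl & !tr$is_target
    brute <- apply(ep$data[sel, , , drop = FALSE], c(2, 3), mean)
    got <- erp$map[[which(erp$cell == cl)]]
    expect_equal(unname(got), unname(brute), tolerance = 1e-12)
    expect_equal(erp$n_trials[erp$cell == cl], sum(sel))
  }
  # two identical trials average to either trial
  ep$data[] <- 0
  ep$data[1, , ] <- 7; ep$data[2, , ] <- 7
  keep2 <- ep
  keep2$trial_table <- tr[1:2, ]
  keep2$trial_table$is_target <- FALSE
  keep2$data <- ep$data[1:2, , , drop = FALSE]
  one_cell <- average_conditions(keep2, by = "cell", require_complete = FALSE)
  expect_true(all(one_cell$map[[1]] == 7))
})

test_that("an emptied cell raises an error naming the cell", {
  m <- tiny_montage()
  spec <- design_spec(categories = "x", trials_per_category = 8,
                      n_stimuli_per_subcategory = 10)
  tr <- build_category_trials(spec, "x")
  ep <- simulate_subject_epochs(tr, list(), noise_spec(trial_noise_sd = 0),
                                m, sampling_rate = 50, seed = 1)
  # saturate every Unexp_Rep trial so rejection empties that cell
  idx <- which(tr$cell == "Unexp_Rep")
  ep$data[idx, 1, 1] <- 500
  pruned <- reject_artifacts(ep)$epochs
  expect_error(average_conditions(pruned), "Unexp_Rep")
})

test_that("average reference commutes with condition averaging", {
  m <- small_montage()
  spec <- design_spec(categories = "x", trials_per_category = 8,
                      n_stimuli_per_subcategory = 10)
  tr <- build_category_trials(spec, "x")
  ep <- simulate_subject_epochs(tr, list(), noise_spec(trial_noise_sd = 5),
                                m, sampling_rate = 50, seed = 2)
  a <- average_conditions(average_reference(ep))
  b <- average_reference(average_conditions(ep))
  for (i in seq_len(nrow(a))) {
    expect_equal(a$map[[i]], b$map[[i]], tolerance = 1e-12)
  }
  # re-referenced condition maps have zero channel mean at every timepoint
  expect_true(all(abs(colMeans(a$map[[1]])) < 1e-9))
})
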