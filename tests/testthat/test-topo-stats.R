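test_that("gfp matches its closed forms and the brute-force formula", {
  expect_equal(gfp(rep(3, 10)), 0)
  expect_equal(gfp(c(1, -1)), 1)
  set.seed(1)
  v <- rnorm(64)
  expect_equal(gfp(v), sqrt(mean((v - mean(v))^2)))
  m <- matrix(rnorm(64 * 5), 64, 5)
  expect_equal(gfp(m), apply(m, 2, function(col) sqrt(mean((col - mean(col))^2))))
})

test_that("gdi is a symmetric nonnegative dissimilarity with the stated closed forms", {
  set.seed(2)
  a <- rnorm(32); b <- rnorm(32); c <- rnorm(32)
  expect_equal(gdi(a, a), 0)
  expect_equal(gdi(c(1, -1), c(-1, 1)), 2)
  expect_equal(gdi(a, b), gdi(b, a))
  expect_gte(gdi(a, b), 0)
  expect_lte(gdi(a, c), gdi(a, b) + gdi(b, c) + 1e-12)
  expect_error(gdi(a, rnorm(16)), "same channels")
})

test_that("gdi equals the gfp of the difference for average-referenced maps", {
  set.seed(3)
  for (i in 1:20) {
    a <- random_avg_ref_map(64)
    b <- random_avg_ref_map(64)
    expect_equal(gdi(a, b), gfp(a - b), tolerance = 1e-12)
  }
})

test_that("GFP normalization yields unit GFP and is scale invariant", {
  set.seed(4)
  m <- matrix(rnorm(32 * 10), 32, 10)
  n1 <- normalize_by_gfp(m)
  expect_equal(gfp(n1), rep(1, 10), tolerance = 1e-9)
  expect_equal(normalize_by_gfp(10 * m), n1, tolerance = 1e-12)
  # gdi of normalized maps invariant to independent positive rescaling
  a <- matrix(rnorm(32), 32, 1); b <- matrix(rnorm(32), 32, 1)
  g0 <- gdi(normalize_by_gfp(a), normalize_by_gfp(b))
  g1 <- gdi(normalize_by_gfp(3.7 * a), normalize_by_gfp(0.2 * b))
  expect_equal(g1, g0, tolerance = 1e-12)
  flat <- m; flat[, 4] <- 2
  expect_error(normalize_by_gfp(flat), "index 4")
})

test_that("identical maps in all conditions give zero statistic and p = 1", {
  base <- matrix(rnorm(8 * 5), 8, 5)
  maps <- lapply(1:4, function(s) {
    stats::setNames(lapply(design_cells, function(c) base), design_cells)
  })
  names(maps) <- sprintf("s%02d", 1:4)
  erps <- erps_from_maps(maps)
  res <- tanova_pointwise(erps, "repetition_main", n_perm = 50, seed = 1)
  expect_equal(res$observed, rep(0, 5))
  expect_equal(res$p, rep(1, 5))
})

test_that("Monte-Carlo p agrees with the exhaustive permutation oracle", {
  # oracle: full enumeration of the 2^6 within-subject swaps for 6 subjects
  # and 2 paired conditions, written independently of the package machinery
  set.seed(7)
  n_sub <- 6
  erps <- simulate_condition_erps(n_subjects = n_sub, n_timepoints = 1,
                                  cells = c("A", "B"), erp_noise_sd = 1,
                                  montage = make_montage(32), seed = 19)
  res <- tanova_pointwise(erps, "between_sets", n_perm = 5000, seed = 23,
                          sets = c("A", "B"))
  d <- sapply(1:n_sub, function(s) {
    erps$map[[which(erps$subject == sprintf("s%02d", s) & erps$cell == "A")]][, 1] -
      erps$map[[which(erps$subject == sprintf("s%02d", s) & erps$cell == "B")]][, 1]
  })
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n_sub)))
  stats_ex <- apply(signs, 1, function(sv) sqrt(mean((d %*% sv / n_sub)^2)))
  obs <- sqrt(mean(rowMeans(d)^2))
  expect_equal(res$observed, obs, tolerance = 1e-12)
  p_exact <- mean(stats_ex >= obs - 1e-12)
  se <- sqrt(p_exact * (1 - p_exact) / res$n_perm)
  expect_lt(abs(res$p - p_exact), 2 * se + 2 / res$n_perm)
})

test_that("pointwise rejection rate is near alpha under the global null", {
  erps <- simulate_condition_erps(n_subjects = 20, n_timepoints = 250, seed = 31)
  res <- tanova_pointwise(erps, "repetition_main", n_perm = 500, seed = 37)
  rate <- mean(res$p < 0.05)
  # 250 autocorrelated timepoints: generous Monte-Carlo tolerance
  expect_lt(abs(rate - 0.05), 0.05)
  expect_true(all(res$p > 0)) # +1 estimator: p is never zero
  # approximate uniformity of the null p-values (sanity, coarse bound)
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))$statistic
  expect_lt(unname(ks), 0.2)
})

test_that("permutation streams are reproducible under a fixed seed", {
  erps <- simulate_condition_erps(n_subjects = 6, n_timepoints = 20, seed = 41)
  a <- tanova_pointwise(erps, "interaction", n_perm = 200, seed = 43)
  b <- tanova_pointwise(erps, "interaction", n_perm = 200, seed = 43)
  expect_identical(a$p, b$p)
  expect_identical(a$perm_stats, b$perm_stats)
  c2 <- tanova_pointwise(erps, "interaction", n_perm = 200, seed = 44)
  expect_false(identical(a$perm_stats, c2$perm_stats))
})

test_that("missing cells and too few subjects are rejected", {
  erps <- simulate_condition_erps(n_subjects = 4, n_timepoints = 5, seed = 47)
  no_cell <- erps[erps$cell != "Unexp_Rep", ]
  no_cell <- as_condition_erp(no_cell, erp_times(erps))
  expect_error(tanova_pointwise(no_cell, "repetition_main", n_perm = 10),
               "Unexp_Rep")
  one_sub <- as_condition_erp(erps[erps$subject == "s01", ], erp_times(erps))
  expect_error(tanova_pointwise(one_sub, "repetition_main", n_perm = 10),
               "2 subjects")
})

test_that("a one-sample window test reduces to the pointwise test at that sample", {
  erps <- simulate_condition_erps(n_subjects = 8, n_timepoints = 10, seed = 53)
  times <- erp_times(erps)
  k <- 4
  win <- tanova_window(erps, c(times[k], times[k]), "repetition_main",
                       n_perm = 300, seed = 59)
  pt <- tanova_pointwise(erps, "repetition_main", n_perm = 300, seed = 59)
  expect_equal(win$observed, pt$observed[k], tolerance = 1e-12)
  expect_equal(win$p, pt$p[k])
})

test_that("identical window means across conditions give p = 1", {
  base <- matrix(rnorm(8 * 6), 8, 6)
  maps <- lapply(1:4, function(s) list(A = base + s, B = base + s))
  names(maps) <- sprintf("s%02d", 1:4)
  erps <- erps_from_maps(maps)
  res <- tanova_window(erps, c(2, 5), "between_sets", n_perm = 100, seed = 61,
                       sets = c("A", "B"))
  expect_equal(res$p, 1)
})

test_that("window tests detect an injected topography difference between categories", {
  # power check: amplitude 3x the noise SD of a window-mean map
  m <- make_montage(32)
  topoA <- make_topography(m, "PO7", 0.4)
  hits <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    maps <- lapply(1:10, function(s) {
      noise <- function() matrix(rnorm(32 * 5), 32, 5)
      list(catA = noise() + 3 * unname(topoA), catB = noise())
    })
    names(maps) <- sprintf("s%02d", 1:10)
    erps <- erps_from_maps(maps)
    res <- tanova_window(erps, c(1, 5), "between_sets", n_perm = 200,
                         seed = 100 + r, sets = c("catA", "catB"))
    hits <- hits + (res$p < 0.05)
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("repetition_difference returns per-category marginal difference maps", {
  erps <- simulate_condition_erps(n_subjects = 3, n_timepoints = 4,
                                  categories = "word", seed = 67)
  d <- repetition_difference(erps)
  expect_equal(nrow(d), 3)
  s1 <- erps[erps$subject == "s01", ]
  brute <- (s1$map[[which(s1$cell == "Exp_Rep")]] +
              s1$map[[which(s1$cell == "Unexp_Rep")]]) / 2 -
    (s1$map[[which(s1$cell == "Exp_Alt")]] +
       s1$map[[which(s1$cell == "Unexp_Alt")]]) / 2
  expect_equal(d$map[[which(d$subject == "s01")]], brute, tolerance = 1e-12)
  expect_equal(d$cell[1], "word")
})

test_that("the restricted permutation scheme is available for main effects only", {
  erps <- simulate_condition_erps(n_subjects = 8, n_timepoints = 15, seed = 87)
  a <- tanova_pointwise(erps, "repetition_main", n_perm = 200, seed = 89,
                        scheme = "restricted")
  b <- tanova_pointwise(erps, "repetition_main", n_perm = 200, seed = 89,
                        scheme = "restricted")
  expect_identical(a$p, b$p)
  expect_true(all(a$p > 0 & a$p <= 1))
  expect_error(tanova_pointwise(erps, "interaction", n_perm = 50,
                                scheme = "restricted"), "main effects only")
})
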