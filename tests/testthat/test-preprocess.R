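test_that("whittaker smoother matches a dense direct solve", {
  # frozen small case
  z <- whittaker_smooth(c(1, 3, 2, 5, 4), rep(1, 5), lam = 1)
  expect_equal(z, brute_whittaker(c(1, 3, 2, 5, 4), rep(1, 5), 1),
               tolerance = 1e-10)
  # random sizes and weights up to n = 50
  set.seed(11)
  for (i in 1:10) {
    n <- sample(5:50, 1)
    y <- rnorm(n)
    w <- runif(n, 0.1, 2)
    lam <- 10^runif(1, -1, 6)
    expect_equal(whittaker_smooth(y, w, lam), brute_whittaker(y, w, lam),
                 tolerance = 1e-8)
  }
})

test_that("whittaker limits: no penalty returns y, huge penalty a line", {
  y <- c(1, 3, 2, 5, 4, 7, 6)
  expect_equal(whittaker_smooth(y, rep(1, 7), 0), y, tolerance = 1e-12)
  z <- whittaker_smooth(y, rep(1, 7), 1e12)
  line <- fitted(lm(y ~ seq_along(y)))
  expect_equal(z, unname(line), tolerance = 1e-4)
  expect_error(whittaker_smooth(y, rep(0, 7), 1),
               class = "sersquant_singular_error")
})

test_that("airPLS follows a peak-free smooth curve and handles zeros", {
  x <- seq_len(2000)
  bump <- 5 * exp(-((x - 1000)^2) / (2 * 500^2))
  est <- airpls_baseline(bump, lam = 1e5)
  expect_lt(max(abs(est - bump)), 0.01 * diff(range(bump)))
  expect_equal(airpls_baseline(rep(0, 100)), rep(0, 100))
  expect_error(airpls_baseline(c(1, NA, 3)), class = "sersquant_value_error")
})

test_that("airPLS recovers a known baseline under tall narrow peaks", {
  x <- seq(239, 2400)
  amp <- 10
  base <- amp * (exp(-((x - 1000)^2) / (2 * 600^2)) + 0.4 * (1 - (x - 239) / 2161))
  peaks <- 50 * exp(-((x - 580)^2) / (2 * 5^2)) +
    40 * exp(-((x - 1400)^2) / (2 * 6^2)) +
    30 * exp(-((x - 1550)^2) / (2 * 5^2))
  est <- airpls_baseline(base + peaks)
  expect_lt(sqrt(mean((est - base)^2)), 0.05 * amp)
  # weights suppress positive residuals: baseline stays at or under the peaks
  peak_region <- abs(x - 1400) < 10
  expect_true(all(est[peak_region] <= (base + peaks)[peak_region] + 0.5))
})

test_that("correct_baseline removes most baseline energy and keeps labels", {
  cfg <- synth_config(seed = 11)
  sim <- generate_spectra(cfg)
  corrected <- correct_baseline(sim$spectra)
  expect_identical(spectra_concentrations(corrected),
                   spectra_concentrations(sim$spectra))
  expect_identical(spectra_axis(corrected), spectra_axis(sim$spectra))
  # residual baseline = (emitted - estimate) - (emitted - true) = true - est
  resid <- spectra_matrix(corrected) -
    (spectra_matrix(sim$spectra) - sim$truth$baseline)
  expect_lt(sum(resid^2) / sum(sim$truth$baseline^2), 0.1)
})

test_that("baseline-free data passes through nearly unchanged", {
  cfg <- synth_config(baseline_amplitude = 0, noise_sd = 0.05,
                      outlier_rate = 0, n_samples = 5, seed = 4)
  sim <- generate_spectra(cfg)
  corrected <- correct_baseline(sim$spectra)
  dev <- abs(spectra_matrix(corrected) - spectra_matrix(sim$spectra))
  # the estimator legitimately assigns a little of the smooth Lorentzian
  # tail mass to background; the subtraction must stay a small fraction of
  # the tallest peak
  expect_lt(max(dev), 0.06 * max(spectra_matrix(sim$spectra)))
})

test_that("window selection keeps exactly the in-window channels", {
  sim <- generate_spectra(synth_config(n_samples = 2, seed = 1))
  sel <- select_windows(sim$spectra)
  # integer axis 239..2400: 99 channels in [519,617], 422 in [1292,1713]
  expect_length(spectra_axis(sel), 521)
  expect_true(all(
    (spectra_axis(sel) >= 519 & spectra_axis(sel) <= 617) |
      (spectra_axis(sel) >= 1292 & spectra_axis(sel) <= 1713)
  ))
  # idempotent
  expect_identical(as.data.frame(select_windows(sel)), as.data.frame(sel))
  # whole-axis window is the identity
  all_w <- window_set(0, 1e5)
  expect_identical(as.data.frame(select_windows(sim$spectra, all_w)),
                   as.data.frame(sim$spectra))
  # empty intersection errors
  expect_error(select_windows(sim$spectra, window_set(0, 1)),
               class = "sersquant_selection_error")
})

test_that("window sets validate ordering and overlap", {
  expect_error(window_set(10, 5), class = "sersquant_config_error")
  expect_error(window_set(c(1, 5), c(6, 9)), class = "sersquant_config_error")
  w <- window_set(c(1292, 519), c(1713, 617))  # sorts itself
  expect_equal(w$lo, c(519, 1292))
})

test_that("min-max scaling is fitted on train only and invertible", {
  sp <- tiny_spectra(4, 6)
  scaler <- fit_scaler(sp, conc_max = 10)
  sc <- scale_spectra(sp, scaler)
  m <- spectra_matrix(sc)
  expect_true(all(m >= 0 & m <= 1))
  back <- scale_spectra(sc, scaler, invert = TRUE)
  expect_equal(spectra_matrix(back), spectra_matrix(sp), tolerance = 1e-12)
  expect_equal(scale_concentration(scale_concentration(7, scaler),
                                   scaler, invert = TRUE), 7)

  # midpoint maps to 0.5
  m2 <- matrix(c(2, 4, 3, 3), nrow = 2)  # channel 1 spans [2,4]
  sp2 <- spectra_from_matrix(m2, c(100, 200), concentrations = c(1, 2))
  sc2 <- fit_scaler(sp2, conc_max = 2)
  mid <- spectra_from_matrix(matrix(c(3, 3), 1), c(100, 200),
                             concentrations = 1)
  expect_equal(unname(spectra_matrix(scale_spectra(mid, sc2))[1, 1]), 0.5)
  # constant channel: no division by zero, maps to 0
  expect_equal(unname(spectra_matrix(scale_spectra(mid, sc2))[1, 2]), 0)
  # out-of-range test values are not clipped
  lo <- spectra_from_matrix(matrix(c(0, 3), 1), c(100, 200),
                            concentrations = 1)
  expect_lt(unname(spectra_matrix(scale_spectra(lo, sc2))[1, 1]), 0)
})

test_that("scale_features fits on train and carries companions", {
  sim <- generate_spectra(synth_config(n_samples = 6, seed = 8))
  sets <- split_spectra(sim$spectra, n_train = 4)
  out <- scale_features(sets$train, test = sets$test)
  expect_named(out, c("train", "test", "scaler"))
  expect_true(all(spectra_matrix(out$train) >= 0 &
                    spectra_matrix(out$train) <= 1))
})

test_that("gradient split is 40/11, disjoint, exhaustive and spans the range", {
  sim <- generate_spectra(synth_config(seed = 21))
  sets <- split_spectra(sim$spectra, n_train = 40)
  train_ids <- spectra_ids(sets$train)
  test_ids <- spectra_ids(sets$test)
  expect_length(train_ids, 40)
  expect_length(test_ids, 11)
  expect_length(intersect(train_ids, test_ids), 0)
  expect_setequal(c(train_ids, test_ids), spectra_ids(sim$spectra))
  # stratified: test concentrations cover the whole gradient
  conc_test <- sort(unname(spectra_concentrations(sets$test)))
  expect_equal(conc_test[1], 1)
  expect_equal(conc_test[11], 100)
  # deterministic
  sets2 <- split_spectra(sim$spectra, n_train = 40)
  expect_identical(spectra_ids(sets2$test), test_ids)
  # random method reproducible under a seed
  r1 <- split_spectra(sim$spectra, n_train = 40, seed = 5, method = "random")
  r2 <- split_spectra(sim$spectra, n_train = 40, seed = 5, method = "random")
  expect_identical(spectra_ids(r1$test), spectra_ids(r2$test))
  # bounds
  expect_error(split_spectra(sim$spectra, n_train = 51),
               class = "sersquant_value_error")
  expect_error(split_spectra(sim$spectra, n_train = 0),
               class = "sersquant_value_error")
})
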