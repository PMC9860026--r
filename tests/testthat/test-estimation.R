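test_that("background noise estimation recovers the complex-channel sigma", {
  ph <- full_phantom()
  acq <- acquisition_params(75, 1200, sigma = 1.0)
  ser <- simulate_series(ph, acq, first_n_echoes(mono97(), 3), seed = 51)
  cm <- corner_masks(ph)
  est <- estimate_noise_background(ser, cm)
  expect_gte(est$n_voxels, 1200)
  expect_gt(est$sigma, 0.95)
  expect_lt(est$sigma, 1.05)
  est_mean <- estimate_noise_background(ser, cm, method = "mean")
  expect_equal(est_mean$sigma, est$sigma, tolerance = 0.03)
  # all-zero background
  zero <- array(0, c(10, 10, 3))
  expect_equal(estimate_noise_background(zero, matrix(TRUE, 10, 10))$sigma, 0)
  expect_error(estimate_noise_background(zero, matrix(FALSE, 10, 10)), "no voxels")
})

test_that("noiseless data are recovered exactly", {
  train <- mono97()
  tis <- roi3_tissue()
  acq <- acquisition_params(75, 1200)
  m <- Mod(noiseless_signal(tis, acq, train))
  fit <- fit_t2star_rician(train, m, sigma = 0)
  expect_lt(abs(fit$t2_star - 69), 1e-5)
  expect_equal(fit$amplitude, steady_state_factor(75, 1200, 878), tolerance = 1e-6)
  expect_true(fit$converged)
  expect_error(fit_t2star_rician(first_n_echoes(train, 2), m[1:2], 0), "3 echoes")
})

test_that("batch fitting agrees with the single-voxel interface", {
  train <- first_n_echoes(bip97(), 20)
  acq <- acquisition_params(75, 1200, sigma = 0.01)
  M <- simulate_voxels(roi3_tissue(), acq, train, 40, seed = 61)
  batch <- fit_t2star_batch(M, train, 0.01)
  for (i in c(1, 13, 40)) {
    single <- fit_t2star_rician(train, M[i, ], 0.01)
    expect_equal(single$t2_star, batch$t2_star[i], tolerance = 1e-8)
    expect_equal(single$amplitude, batch$amplitude[i], tolerance = 1e-8)
  }
})

test_that("the fit is scale-equivariant and echo-order invariant", {
  train <- mono97()
  acq <- acquisition_params(75, 1200, sigma = 0.01)
  m <- as.vector(simulate_voxels(roi3_tissue(), acq, train, 1, seed = 62))
  base <- fit_t2star_rician(train, m, 0.01)
  for (c_scale in c(0.1, 7)) {
    sc <- fit_t2star_rician(train, c_scale * m, c_scale * 0.01)
    expect_equal(sc$t2_star, base$t2_star, tolerance = 1e-6)
    expect_equal(sc$amplitude, c_scale * base$amplitude, tolerance = 1e-6)
  }
})

test_that("the Rician fit degenerates to least squares at high SNR", {
  train <- mono97()
  acq <- acquisition_params(75, 1200, sigma = 1e-4)  # min SNR ~ 1900
  m <- as.vector(simulate_voxels(roi3_tissue(), acq, train, 1, seed = 63))
  ric <- fit_t2star_rician(train, m, 1e-4)
  lsq <- fit_t2star_rician(train, m, 1e-4,
                           options = fit_options(noise_model = "gaussian"))
  expect_equal(ric$t2_star, lsq$t2_star, tolerance = 1e-3 * 69)
  expect_lt(abs(ric$t2_star - lsq$t2_star) / lsq$t2_star, 0.001)
})

test_that("map fitting masks background with NA sentinels", {
  ph <- small_phantom()
  train <- first_n_echoes(mono97(), 8)
  acq <- acquisition_params(75, 1200, sigma = 0)
  ser <- simulate_series(ph, acq, train)
  fit <- fit_t2star_map(ser, sigma = 0)
  for (k in 1:5) {
    vals <- fit$t2_star[region_mask(ph, k)]
    expect_equal(unique(round(vals, 6)), ph$regions$t2_star[k])
  }
  expect_true(all(is.na(fit$t2_star[ph$label_map == 0L])))
})

test_that("Rician fitting shrinks the low-SNR noise-floor bias of T2*", {
  train <- mono97()
  tis <- roi3_tissue()
  amp <- steady_state_factor(75, 1200, 878)
  sig <- amp * exp(-3.84 / 69) / 3      # first-echo SNR = 3
  acq <- acquisition_params(75, 1200, sigma = sig)
  M <- simulate_voxels(tis, acq, train, 3000, seed = 64)
  ric <- fit_t2star_batch(M, train, sig)$t2_star
  lsq <- fit_t2star_batch(M, train, sig,
                          options = fit_options(noise_model = "gaussian"))$t2_star
  expect_lt(abs(mean(ric) - 69), abs(mean(lsq) - 69))
  # the plain magnitude fit overestimates T2* (noise floor flattens the tail)
  expect_gt(mean(lsq), 69)
})

test_that("amplitude-modulation correction recovers injected factors", {
  train <- bip97()
  tis <- roi3_tissue()
  acq0 <- acquisition_params(75, 1200, sigma = 0)
  m0 <- Mod(noiseless_signal(tis, acq0, train))
  # unmodulated noiseless input: factors stay at one, data unchanged
  res0 <- correct_amplitude_modulation(m0, train, sigma = 0, mode = "pooled")
  expect_equal(res0$modulation$g_odd, 1, tolerance = 1e-6)
  expect_equal(res0$modulation$g_even, 1, tolerance = 1e-6)
  expect_equal(as.vector(res0$corrected), m0, tolerance = 1e-6)
  # injected 1.05/0.95 at moderate noise, pooled estimation
  amp <- steady_state_factor(75, 1200, 878)
  sig <- amp * exp(-3.84 / 69) / 50
  acq <- acquisition_params(75, 1200, sigma = sig)
  M <- simulate_voxels(tis, acq, train, 300, mod = parity_modulation(1.05, 0.95),
                       seed = 65)
  res <- correct_amplitude_modulation(M, train, sig, mode = "pooled")
  expect_equal(res$modulation$g_odd / res$modulation$g_even, 1.05 / 0.95,
               tolerance = 1e-2)
  # correction reduces the T2* bias relative to fitting the raw data
  raw <- fit_t2star_batch(M, train, sig)$t2_star
  expect_lt(abs(mean(res$fit$t2_star) - 69), abs(mean(raw) - 69))
})

test_that("modulation correction refuses constant-parity trains", {
  m <- Mod(noiseless_signal(roi3_tissue(), acquisition_params(75, 1200), mono97()))
  expect_error(correct_amplitude_modulation(m, mono97(), 0), "not applicable")
  # an evenly-strided bipolar train has lost its parity alternation too
  strided <- every_nth_echo(bip97(), 2)
  ms <- Mod(noiseless_signal(roi3_tissue(), acquisition_params(75, 1200), strided))
  expect_error(correct_amplitude_modulation(ms, strided, 0), "not applicable")
})

test_that("the scoring iteration maximises the Rician likelihood", {
  # independent route: generic box-constrained quasi-Newton on the
  # negative log-likelihood must land on the same optimum
  train <- first_n_echoes(mono97(), 16)
  sig <- 0.02
  M <- simulate_voxels(roi3_tissue(), acquisition_params(75, 1200, sig),
                       train, 5, seed = 66)
  batch <- fit_t2star_batch(M, train, sig)
  for (i in 1:5) {
    o <- stats::optim(c(batch$amplitude[i] * 1.2, batch$t2_star[i] * 0.8),
                      function(p) -sum(rician_loglik(M[i, ],
                                                     p[1] * exp(-train$te / p[2]),
                                                     sig)),
                      method = "L-BFGS-B", lower = c(1e-9, 1), upper = c(Inf, 1000),
                      control = list(factr = 1e3))
    expect_equal(o$par[2], batch$t2_star[i], tolerance = 1e-5)
    expect_equal(-o$value, -batch$objective[i], tolerance = 1e-8)
  }
})
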