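test_that("Gaussian Fisher matrix obeys rank, scaling and additivity laws", {
  train <- mono97()
  expect_error(fisher_gaussian(echo_train(3.84, "odd"), 1, 69, 0.01), "rank")
  f1 <- predict_std(fisher_gaussian(train, 0.77, 69, 0.01))
  f2 <- predict_std(fisher_gaussian(train, 0.77, 69, 0.02))
  expect_equal(f2$std_t2star / f1$std_t2star, 2, tolerance = 1e-12)
  # duplicating every echo doubles the information: std / sqrt(2)
  dup <- echo_train(sort(c(train$te, train$te + 1e-7)),
                    rep("odd", 2 * train$n_e))
  fd <- predict_std(fisher_gaussian(dup, 0.77, 69, 0.01))
  expect_equal(fd$std_t2star, f1$std_t2star / sqrt(2), tolerance = 1e-4)
  # diagonal matrix sanity for the inverse
  fim <- structure(matrix(c(4, 0, 0, 25), 2, 2,
                          dimnames = list(c("amplitude", "t2_star"),
                                          c("amplitude", "t2_star"))),
                   class = c("fisher_matrix", "matrix"), regime = "gaussian")
  expect_equal(predict_std(fim)$std_t2star, 1 / 5)
  expect_equal(predict_std(fim)$std_amplitude, 1 / 2)
})

test_that("Rician Fisher information converges to Gaussian at high SNR", {
  train <- first_n_echoes(mono97(), 10)
  t2 <- 1e6             # nearly flat decay keeps every echo at the same SNR
  sigma <- 0.02
  amp <- 50 * sigma     # per-echo SNR 50
  fr <- unclass(fisher_rician(train, amp, t2, sigma, snr_gaussian_limit = 1e9))
  fg <- unclass(fisher_gaussian(train, amp, t2, sigma))
  expect_lt(max(abs(fr - fg) / abs(fg)), 0.01)
})

test_that("low SNR loses information relative to the Gaussian formula", {
  train <- first_n_echoes(mono97(), 12)
  sigma <- 0.1
  amp <- sigma * 1 / exp(-3.84 / 69)    # first-echo SNR = 1
  r <- predict_std(fisher_rician(train, amp, 69, sigma))
  g <- predict_std(fisher_gaussian(train, amp, 69, sigma))
  expect_gt(r$std_t2star, g$std_t2star)
  # simulation-based oracle for the per-observation information at nu/sigma = 1:
  # variance of the central-difference score of the analytic log-density
  nu <- 0.1; s <- 0.1; h <- 1e-4
  set.seed(71)
  m <- sqrt(rnorm(4e5, nu, s)^2 + rnorm(4e5, 0, s)^2)
  logp <- function(m, v) log(m / s^2) - (m^2 + v^2) / (2 * s^2) +
    log(besselI(m * v / s^2, 0, expon.scaled = TRUE)) + m * v / s^2
  info_mc <- var((logp(m, nu + h) - logp(m, nu - h)) / (2 * h))
  expect_equal(rician_nu_information(nu, s), info_mc, tolerance = 0.05)
  # no signal, no information about the decay
  expect_error(fisher_rician(train, 0, 69, sigma), "singular|positive")
})

test_that("sigma calibration round-trips and scales near-linearly", {
  train <- mono97()
  tis <- roi3_tissue()
  acq <- acquisition_params(75, 1200)
  target <- crlb_t2star_std(train, tis, acq, sigma = 0.012)
  expect_equal(calibrate_sigma(target, train, tis, acq), 0.012,
               tolerance = 1e-6)
  s1 <- calibrate_sigma(1.0, train, tis, acq)
  s2 <- calibrate_sigma(2.0, train, tis, acq)
  expect_equal(s2 / s1, 2, tolerance = 0.005)
  expect_error(calibrate_sigma(1.0, train, tis, acq, interval = c(1e-6, 2e-6)),
               "bracket")
})

test_that("matched echo spacings predict matched precision", {
  # every-2nd monopolar echo (dTE 5.84 ms) vs every-4th bipolar echo
  # (dTE 5.88 ms) over the same 92 ms range
  tis <- roi3_tissue()
  acq <- acquisition_params(75, 1200)
  s0 <- calibrated_sigma0()
  m <- every_nth_echo(mono97(), 2)
  b <- every_nth_echo(bip97(), 4)
  expect_equal(m$delta_te, 5.84)
  expect_equal(b$delta_te, 5.88)
  sm <- crlb_t2star_std(m, tis, acq, sigma = s0)
  sb <- crlb_t2star_std(b, tis, acq, sigma = s0)
  expect_lt(abs(sm - sb) / sm, 0.02)
})

test_that("bandwidth-coupled noise favours the low-bandwidth bipolar readout", {
  # with sigma scaling as sqrt(BW), bipolar at 342 Hz/px collects as many
  # echoes as monopolar at 718 Hz/px but at higher SNR
  tis <- roi3_tissue()
  acq <- acquisition_params(75, 1200)
  s0 <- calibrated_sigma0()
  mono718 <- preset_train("bw718", "monopolar")
  bip342 <- preset_train("bw342", "bipolar")
  expect_identical(mono718$n_e, bip342$n_e)   # 31 echoes each
  std_m <- crlb_t2star_std(mono718, tis, acq, sigma = noise_sigma(s0, 718, 801))
  std_b <- crlb_t2star_std(bip342, tis, acq, sigma = noise_sigma(s0, 342, 801))
  expect_lt(std_b, std_m)
})

test_that("flip-angle rescaling moves the Gaussian bound inversely", {
  train <- mono97()
  tis <- roi3_tissue()
  s <- 0.005
  r75 <- crlb_t2star_std(train, tis, acquisition_params(75, 1200), sigma = s,
                         noise = "gaussian")
  r15 <- crlb_t2star_std(train, tis, acquisition_params(15, 1200), sigma = s,
                         noise = "gaussian")
  ratio_ssf <- steady_state_factor(75, 1200, 878) / steady_state_factor(15, 1200, 878)
  expect_equal(r15 / r75, ratio_ssf, tolerance = 0.01)
})

test_that("the R2* precision transfer applies the analytic Jacobian", {
  expect_equal(t2star_to_r2star_std(1.08, 69), 1.08 / 69^2)
})
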