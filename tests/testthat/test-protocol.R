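test_that("acquisition window is n_x/BW rounded up to the raster", {
  # 240 samples at 801 Hz/px x 240 px: 1.24844 ms -> 1.25 ms
  expect_equal(acquisition_time(240, 801 * 240), 1.25)
  # exact multiple stays put
  expect_equal(acquisition_time(192, 192000), 1.00)
  # 342 Hz/px: 2.92398 ms -> 2.93 ms
  expect_equal(acquisition_time(240, 342 * 240), 2.93)
  # coarser raster rounds further up
  expect_equal(acquisition_time(240, 801 * 240, raster = 0.1), 1.3)
  expect_error(acquisition_time(0, 1000), "n_x")
  expect_error(acquisition_time(10, -1), "positive")
})

test_that("TE schedules reproduce the published first echo and spacings", {
  timing <- gradient_timing(t_prep = 3.105, t_ramp = 0.11, t_fb = 1.45)
  bip <- te_schedule(timing, t_acq = 1.25, scheme = "bipolar", n_e = 3)
  expect_equal(bip$te, c(3.84, 5.31, 6.78))
  expect_equal(bip$parity, c("odd", "even", "odd"))
  mono <- te_schedule(timing, t_acq = 1.25, scheme = "monopolar", n_e = 2)
  expect_equal(mono$te, c(3.84, 6.76))
  expect_equal(mono$delta_te, 2.92)
  expect_equal(mono$parity, c("odd", "odd"))
  expect_error(te_schedule(timing, 1.25, "monopolar", 0), "n_e")
})

test_that("zero fly-back collapses monopolar onto bipolar timing", {
  timing <- gradient_timing(t_prep = 3.105, t_ramp = 0.11, t_fb = 0)
  m <- te_schedule(timing, 1.25, "monopolar", 6)
  b <- te_schedule(timing, 1.25, "bipolar", 6)
  expect_equal(m$te, b$te)
})

test_that("monopolar-bipolar TE difference is (n-1) fly-back durations", {
  set.seed(42)
  for (i in 1:20) {
    timing <- gradient_timing(t_prep = runif(1, 1, 5), t_ramp = runif(1, 0.05, 0.3),
                              t_fb = runif(1, 0.2, 2))
    t_acq <- runif(1, 0.5, 3)
    n_e <- sample(2:12, 1)
    m <- te_schedule(timing, t_acq, "monopolar", n_e)
    b <- te_schedule(timing, t_acq, "bipolar", n_e)
    expect_equal(m$te - b$te, (seq_len(n_e) - 1) * timing$t_fb)
  }
})

test_that("echo counting uses the inclusive TE-range boundary", {
  expect_identical(count_echoes(3.84, 2.92, 97), 32L)
  expect_identical(count_echoes(3.84, 1.47, 97), 64L)
  expect_identical(count_echoes(3.84, 2.92, 43), 14L)
  expect_identical(count_echoes(3.84, 1.47, 43), 27L)
  expect_identical(count_echoes(3.84, 2.92, 2.0), 0L)
  # boundary is inclusive: a TE landing exactly on te_max counts
  expect_identical(count_echoes(2, 2, 10), 5L)
  expect_error(count_echoes(3.84, 0, 97), "delta_te")
})

test_that("echo counting is monotone in range and spacing", {
  for (te_max in seq(5, 100, by = 7)) {
    expect_gte(count_echoes(3.84, 2.92, te_max + 3), count_echoes(3.84, 2.92, te_max))
    expect_lte(count_echoes(3.84, 3.5, te_max), count_echoes(3.84, 2.92, te_max))
  }
  # the counted train fills the range: last TE <= te_max < next TE
  for (te_max in c(26, 43, 52, 92, 97)) {
    n <- count_echoes(3.84, 1.47, te_max)
    tr <- train_from_protocol(3.84, 1.47, "bipolar", n_e = n + 1)
    expect_lte(tr$te[n], te_max)
    expect_gt(tr$te[n + 1], te_max)
  }
})

test_that("protocol timing inversion round-trips through the schedule", {
  tm <- timing_from_protocol(3.84, 2.92, 1.47, 1.25)
  expect_equal(tm$t_ramp, 0.11)
  expect_equal(tm$t_fb, 1.45)
  expect_equal(tm$t_prep, 3.105)
  tm2 <- timing_from_protocol(4.62, 4.48, 3.03, 2.93)
  expect_equal(tm2$t_ramp, 0.05)
  expect_equal(tm2$t_fb, 1.45)
  expect_equal(tm2$t_prep, 3.105)
  # boundary: spacing equal to the acquisition window leaves no ramp
  expect_equal(timing_from_protocol(3, 2.5, 2.0, 2.0)$t_ramp, 0)
  expect_error(timing_from_protocol(3.84, 1.0, 1.47, 1.25), "inconsistent")
  # round trip: regenerate TE1 and both spacings
  for (p in list(c(3.84, 2.92, 1.47, 1.25), c(4.62, 4.48, 3.03, 2.93),
                 c(3.9, 3.05, 1.6, 1.26), c(4.0, 3.27, 1.82, 1.42))) {
    tm <- timing_from_protocol(p[1], p[2], p[3], p[4])
    m <- te_schedule(tm, p[4], "monopolar", 4)
    b <- te_schedule(tm, p[4], "bipolar", 4)
    expect_equal(m$te[1], p[1], tolerance = 1e-9)
    expect_equal(m$delta_te, p[2], tolerance = 1e-9)
    expect_equal(b$delta_te, p[3], tolerance = 1e-9)
  }
})

test_that("noise scales with the square root of bandwidth", {
  expect_equal(noise_sigma(1, 500, 500), 1)
  expect_equal(noise_sigma(1, 2000, 500), 2)
  expect_equal(noise_sigma(1, 342 * 240, 801 * 240), sqrt(342 / 801))
  expect_equal(noise_sigma(1, 342 * 240, 801 * 240), 0.6534, tolerance = 1e-4)
  expect_error(noise_sigma(0, 1, 1), "positive")
})

test_that("train subsetting preserves timing and parity structure", {
  b <- bip97()
  f <- first_n_echoes(b, 14)
  expect_equal(f$te, b$te[1:14])
  expect_equal(f$parity, b$parity[1:14])
  e2 <- every_nth_echo(b, 2)
  expect_equal(e2$delta_te, 2 * b$delta_te)
  # even stride on a bipolar train lands on one polarity only
  expect_length(unique(e2$parity), 1L)
  e3 <- every_nth_echo(b, 3)
  expect_length(unique(e3$parity), 2L)
  expect_error(first_n_echoes(b, 0), "out of range")
})

test_that("shipped presets regenerate the published protocols", {
  p <- protocol_presets()
  expect_setequal(p$name, c("bw801", "bw718", "bw613", "bw342"))
  tr <- preset_train("bw801", "monopolar")
  expect_identical(tr$n_e, 32L)
  expect_equal(tr$te[1], 3.84)
  expect_identical(preset_train("bw801", "bipolar", te_max = 43)$n_e, 27L)
  expect_error(preset_train("bw9000", "monopolar"), "unknown")
})
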