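test_that("sampled_signal validates its invariants", {
  expect_error(sampled_signal(matrix(1:6, 3), c("a"), 128), "labels")
  expect_error(sampled_signal(1:5, "a", 0), "rate_hz")
  expect_error(sampled_signal(c(1, NA, 3), "a", 128), "missing")
  s <- sampled_signal(matrix(1:6, 3), c("a", "b"), 128, t0_s = 0.5)
  expect_equal(n_frames(s), 3L)
  expect_equal(signal_times(s), 0.5 + (0:2) / 128)
  expect_equal(signal_channel(s, "b")$values[, 1], c(4, 5, 6))
})

test_that("low-pass Butterworth has unit DC gain and the analytic magnitude", {
  const <- sampled_signal(rep(5, 512), "x", 128)
  for (zp in c(TRUE, FALSE)) {
    out <- lowpass_butterworth(const, 10, zero_phase = zp)
    expect_equal(out$values[, 1], rep(5, 512))
  }

  # sampling well above the cutoff keeps bilinear-transform warping of the
  # digital filter below the comparison tolerance
  # single-pass gain at f = fc is the -3 dB point: |H| = 2^(-1/2)
  s <- sine_signal(32, 4096, 4)
  out <- lowpass_butterworth(s, 32, order = 4, zero_phase = FALSE)
  expect_equal(steady_amplitude(out$values[, 1], 32, 4096), 1 / sqrt(2),
               tolerance = 0.005)

  # at 2 fc, order 4: |H| = (1 + 2^8)^(-1/2) = 1/sqrt(257)
  s2 <- sine_signal(64, 4096, 4)
  out2 <- lowpass_butterworth(s2, 32, order = 4, zero_phase = FALSE)
  expect_equal(steady_amplitude(out2$values[, 1], 64, 4096), 1 / sqrt(257),
               tolerance = 0.005)

  # zero-phase filtering applies the magnitude twice
  out3 <- lowpass_butterworth(s, 32, order = 4, zero_phase = TRUE)
  expect_equal(steady_amplitude(out3$values[, 1], 32, 4096), 1 / 2,
               tolerance = 0.005)
})

test_that("filter rejects invalid cutoffs and degenerate inputs", {
  s <- sine_signal(5, 128, 2)
  expect_error(lowpass_butterworth(s, 64), "Nyquist")
  expect_error(lowpass_butterworth(s, 70), "Nyquist")
  short <- sampled_signal(rnorm(8), "x", 128)
  expect_error(lowpass_butterworth(short, 10), "too short")
})

test_that("zero-phase filtering introduces no lag on a symmetric pulse", {
  n <- 512
  pulse <- exp(-((seq_len(n) - 256) / 20)^2)
  s <- sampled_signal(pulse, "x", 128)
  out <- lowpass_butterworth(s, 10, zero_phase = TRUE)
  expect_equal(which.max(out$values[, 1]), which.max(pulse))
})

test_that("resampling preserves rate conversion, duration and tone", {
  s <- sine_signal(5, 100, 2)
  same <- resample_uniform(s, 100)
  expect_identical(same$values, s$values)

  up <- resample_uniform(s, 128)
  expect_equal(up$rate_hz, 128)
  expect_equal(n_frames(up), 256L)     # 2 s at 128 Hz
  expect_equal(up$t0_s, s$t0_s)
  # dominant spectral peak stays at 5 Hz within one DFT bin
  sp <- Mod(stats::fft(up$values[, 1]))[1:128]
  peak_hz <- (which.max(sp) - 1) * 128 / 256
  expect_equal(peak_hz, 5, tolerance = 128 / 256)

  s200 <- sine_signal(5, 200, 2)
  down <- resample_uniform(s200, 128)
  expect_equal(n_frames(down), 256L)
  expect_lt(abs(n_frames(down) / 128 - 2), 1 / 128)

  expect_error(resample_uniform(s, -5), "positive")
  expect_error(resample_uniform(sampled_signal(1, "x", 10), 20), "2 frames")
})

test_that("resampling round trip reproduces band-limited content within 1% RMS", {
  x <- smooth_noise(400, rate_hz = 128, cutoff_hz = 8, seed = 3)
  s <- sampled_signal(x, "x", 128)
  back <- resample_uniform(resample_uniform(s, 100), 128)
  n <- min(n_frames(back), 400)
  rel <- sqrt(mean((back$values[1:n, 1] - x[1:n])^2)) / sqrt(mean(x^2))
  expect_lt(rel, 0.01)
})

test_that("gravity removal subtracts the configured baseline offset", {
  g <- sampled_signal(rep(9.81, 256), "acc_z", 128)
  expect_equal(remove_gravity(g)$values[, 1], rep(0, 256))

  # sine + offset over an integer number of periods: mean ~ 0 afterwards
  t <- (0:255) / 128
  s <- sampled_signal(sin(2 * pi * 4 * t) + 9.81, "acc_z", 128)
  out <- remove_gravity(s)
  expect_lt(abs(mean(out$values[, 1])), 1e-9)
  expect_equal(out$values[, 1], sin(2 * pi * 4 * t), tolerance = 1e-9)

  # baseline window over a quiet segment maps that segment to ~ 0
  x <- c(rep(9.81, 100), 9.81 + 5 * sin(2 * pi * 3 * (0:155) / 128))
  s2 <- sampled_signal(x, "acc_z", 128)
  out2 <- remove_gravity(s2, baseline = c(0, 100))
  expect_equal(mean(out2$values[1:100, 1]), 0, tolerance = 1e-12)

  expect_error(remove_gravity(s2, baseline = c(50, 50)), "empty")
})

test_that("cropping uses half-open 0-based windows and shifts the clock", {
  ramp <- sampled_signal(0:9, "x", 128, t0_s = 1)
  expect_identical(crop_frames(ramp, 0, 10)$values, ramp$values)
  expect_equal(crop_frames(ramp, 2, 5)$values[, 1], c(2, 3, 4))
  long <- sampled_signal(rnorm(300), "x", 128, t0_s = 1)
  expect_equal(crop_frames(long, 128, 300)$t0_s, 2)
  expect_error(crop_frames(ramp, 5, 3), "out of range")
  expect_error(crop_frames(ramp, 0, 11), "out of range")
})

test_that("crop composition matches a single combined crop", {
  s <- sampled_signal(rnorm(100), "x", 128)
  a <- 10; b <- 80; c <- 5; d <- 40
  twice <- crop_frames(crop_frames(s, a, b), c, d)
  once <- crop_frames(s, a + c, a + d)
  expect_equal(twice$values, once$values)
  expect_equal(twice$t0_s, once$t0_s)
})

test_that("signal CSV round trip is lossless", {
  s <- sampled_signal(matrix(rnorm(60), 20), c("a", "b", "c"), 128,
                      t0_s = 0.25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_signal_csv(s, path)
  back <- read_signal_csv(path)
  expect_equal(back$labels, s$labels)
  expect_equal(back$rate_hz, s$rate_hz)
  expect_equal(back$t0_s, s$t0_s)
  expect_equal(back$values, s$values, tolerance = 1e-12)
})
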