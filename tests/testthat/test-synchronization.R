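test_that("spike window detection finds an injected oscillation burst", {
  n <- 2048
  x <- rep(0, n)
  idx <- 257:896                     # frames [256, 896): 5 cycles at 1 Hz
  x[idx] <- sin(2 * pi * 1 * (0:639) / 128)
  set.seed(1)
  s <- sampled_signal(x + rnorm(n, 0, 0.01), "x", 128)
  w <- find_spike_window(s, min_cycles = 5, band_hz = c(0.5, 3))
  expect_true(w$detected)
  overlap <- min(w$end, 896) - max(w$start, 256)
  expect_gte(overlap / (896 - 256), 0.9)
})

test_that("spike window detection fails gracefully on pure noise", {
  set.seed(2)
  s <- sampled_signal(rnorm(2048), "x", 128)
  w <- find_spike_window(s)
  expect_false(w$detected)
  expect_equal(c(w$start, w$end), c(0L, 2048L))
})

test_that("a burst at the very start yields a window starting at frame 0", {
  n <- 2048
  x <- rep(0, n)
  x[1:640] <- sin(2 * pi * 1 * (0:639) / 128)
  s <- sampled_signal(x, "x", 128)
  w <- find_spike_window(s)
  expect_true(w$detected)
  expect_equal(w$start, 0L)
})

test_that("estimate_delay recovers known integer offsets", {
  x <- smooth_noise(2000, seed = 11)
  ref <- sampled_signal(x[501:1700], "x", 128)
  same <- estimate_delay(ref, ref)
  expect_equal(same$lag_frames, 0L)
  expect_equal(same$peak_correlation, 1, tolerance = 1e-9)

  for (k in c(-153, -5, 37, 211)) {
    other <- sampled_signal(x[(501 - k):(1700 - k)], "x", 128)
    res <- estimate_delay(ref, other)
    expect_identical(res$lag_frames, as.integer(k))
    # brute-force oracle: correlation maximized at the same lag
    brute <- sapply(-300:300, function(l) {
      i <- 301:900
      stats::cor(x[501:1700][i], x[(501 - k):(1700 - k)][i + l])
    })
    expect_identical(res$lag_frames, as.integer((-300:300)[which.max(brute)]))
  }
})

test_that("estimate_delay is exact under 10% noise and antisymmetric", {
  x <- smooth_noise(2400, seed = 21)
  sdx <- stats::sd(x)
  for (seed in 1:20) {
    set.seed(seed)
    k <- sample(c(-400:400), 1)
    ref <- sampled_signal(x[501:1900] + rnorm(1400, 0, 0.1 * sdx), "x", 128)
    oth <- sampled_signal(x[(501 - k):(1900 - k)] + rnorm(1400, 0, 0.1 * sdx),
                          "x", 128)
    res <- estimate_delay(ref, oth, max_lag = 450)
    expect_identical(res$lag_frames, as.integer(k))
    back <- estimate_delay(oth, ref, max_lag = 450)
    expect_identical(back$lag_frames, as.integer(-k))
  }
})

test_that("estimate_delay accounts for t0 so crops report the full-stream lag", {
  x <- smooth_noise(2000, seed = 31)
  ref <- sampled_signal(x[501:1700], "x", 128)
  k <- 64
  oth <- sampled_signal(x[(501 - k):(1700 - k)], "x", 128)
  rc <- crop_frames(ref, 100, 900)
  oc <- crop_frames(oth, 250, 1000)
  res <- estimate_delay(rc, oc)
  expect_identical(res$lag_frames, as.integer(k))
})

test_that("estimate_delay validates its inputs", {
  a <- sampled_signal(rnorm(100), "x", 128)
  b <- sampled_signal(rnorm(100), "x", 100)
  expect_error(estimate_delay(a, b), "rate mismatch")
  expect_error(estimate_delay(a, sampled_signal(rnorm(10), "x", 128)),
               "32 frames")
  flat <- sampled_signal(rep(1, 100), "x", 128)
  expect_error(estimate_delay(a, flat), "constant")
})

test_that("polarity inversion flips the reported peak correlation sign", {
  x <- smooth_noise(1000, seed = 41)
  ref <- sampled_signal(x, "x", 128)
  inv <- sampled_signal(-x, "x", 128)
  res <- estimate_delay(ref, inv, invert_other = TRUE)
  expect_identical(res$lag_frames, 0L)
  expect_equal(res$peak_correlation, 1, tolerance = 1e-9)
})

test_that("alignment shifts clocks, changes no values, and is idempotent", {
  x <- smooth_noise(2000, seed = 51)
  ref <- sampled_signal(x[501:1700], "x", 128)
  k <- 64L
  oth <- sampled_signal(x[(501 - k):(1700 - k)], "x", 128)
  res <- estimate_delay(ref, oth)
  expect_identical(res$lag_frames, k)
  expect_equal(res$lag_s, 0.5)

  aligned <- align_streams(list(oth), res)
  expect_equal(aligned[[1]]$t0_s, -0.5)
  expect_identical(aligned[[1]]$values, oth$values)

  zero <- estimate_delay(ref, aligned[[1]])
  expect_identical(zero$lag_frames, 0L)

  # zero lag leaves clocks untouched
  same <- align_streams(list(ref, oth), estimate_delay(ref, ref))
  expect_equal(same[[1]]$t0_s, ref$t0_s)
  expect_equal(same[[2]]$t0_s, oth$t0_s)
})

test_that("sync_streams recovers a session's true clock offset end to end", {
  spec <- small_spec(seed = 9)
  s <- simulate_session(spec, 1)
  res <- sync_streams(s$marker, signal_channel(s$imu$sa, "acc_z"))
  expect_identical(res$lag_frames, as.integer(s$truth$offset_frames))
  expect_gt(res$peak_correlation, 0.99)
})
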