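test_that("the ground-truth mapping matches an independent re-implementation", {
  m <- default_mapping()
  set.seed(6)
  for (i in 1:20) {
    u1 <- rnorm(18, 0, 10); u2 <- rnorm(18, 0, 10)
    got <- true_mapping(rbind(u1, u2), m)
    want <- numeric(6)
    for (j in 1:6) {
      acc <- m$c[j]
      for (s in 1:18) {
        acc <- acc + m$W1[j, s] * tanh(m$alpha * u1[s]) + m$W2[j, s] * u2[s]
      }
      want[j] <- acc
    }
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("mapping limits behave as designed", {
  m <- default_mapping()
  u <- matrix(rnorm(36, 0, 5), 2, 18)
  # zero weights: outputs equal the offsets
  m0 <- m; m0$W1[] <- 0; m0$W2[] <- 0
  expect_equal(unname(true_mapping(u, m0)), m0$c)
  # alpha -> 0: the tanh branch vanishes
  ms <- m; ms$alpha <- 1e-12
  expect_equal(unname(true_mapping(u, ms)),
               unname(as.numeric(ms$W2 %*% u[2, ] + ms$c)), tolerance = 1e-9)
  expect_error(true_mapping(u[1, , drop = FALSE], m), "u_history")
  # misspecified cohorts carry a delay-3 term and demand a third row
  spec3 <- cohort_spec(n_subjects = 1, misspecify = TRUE)
  expect_error(true_mapping(u, spec3$mapping), "3 rows")
})

test_that("sessions are deterministic in the cohort seed", {
  s1 <- simulate_session(small_spec(seed = 3), 1)
  s2 <- simulate_session(small_spec(seed = 3), 1)
  expect_identical(s1$imu$sa$values, s2$imu$sa$values)
  expect_identical(s1$grf_right$values, s2$grf_right$values)
  expect_identical(s1$truth$offset_frames, s2$truth$offset_frames)
  s3 <- simulate_session(small_spec(seed = 4), 1)
  expect_false(identical(s1$imu$sa$values, s3$imu$sa$values))
})

test_that("cohort draws respect the configured ranges", {
  spec <- cohort_spec(n_subjects = 11, jumps_per_subject = 10, seed = 2)
  cohort <- simulate_cohort(spec)
  expect_length(cohort$sessions, 11L)
  masses <- vapply(cohort$sessions, function(s) s$mass_kg, numeric(1))
  expect_true(all(masses >= 50 & masses <= 85))
  offsets <- vapply(cohort$sessions, function(s) s$truth$offset_frames,
                    numeric(1))
  expect_true(all(offsets >= -500 & offsets <= 500))
  expect_true(all(offsets == round(offsets)))
  durations <- unlist(lapply(cohort$sessions, function(s) {
    s$truth$contact_windows$duration_s
  }))
  expect_length(durations, 110L)
  # detected-at-10-N durations can only be marginally inside the drawn range
  expect_true(all(durations > 0.2 & durations < 0.5))
  expect_length(cohort$manifest$subjects, 11L)
})

test_that("clean target series equal the mapping applied to clean IMU samples", {
  s <- simulate_session(small_spec(seed = 8), 2)
  U <- s$truth$u_clean
  Y <- s$truth$y_clean
  rows <- sample(3:nrow(U), 40)
  for (t in rows) {
    expect_equal(unname(Y[t, ]),
                 unname(true_mapping(rbind(U[t - 1, ], U[t - 2, ]),
                                     s$truth$mapping)),
                 tolerance = 1e-12)
  }
})

test_that("a noise-free session reproduces its bookkeeping exactly", {
  spec <- small_spec(seed = 12, imu_noise_sd = 0, target_noise_sd = 1e-12,
                     grf_noise_sd_n = 1e-9)
  s <- simulate_session(spec, 1)
  vgrf <- sampled_signal(
    s$grf_right$values[, "grf_z"] + s$grf_left$values[, "grf_z"],
    "vgrf", 200)
  ph <- detect_contact_phases(vgrf, subject_id = s$subject_id)
  tw <- s$truth$contact_windows
  expect_length(ph, nrow(tw))
  for (j in seq_along(ph)) {
    expect_equal(ph[[j]]$start_frame, tw$start_frame[j])
    expect_equal(ph[[j]]$end_frame, tw$end_frame[j])
  }
})

test_that("the generated GRF peaks span the configured 2-4 body-weight range", {
  spec <- cohort_spec(n_subjects = 4, jumps_per_subject = 8, seed = 6)
  cohort <- simulate_cohort(spec)
  ratios <- unlist(lapply(cohort$sessions, function(s) {
    bw <- s$mass_kg * 9.81
    vapply(seq_len(nrow(s$truth$contact_windows)), function(j) {
      w <- s$truth$contact_windows[j, ]
      seg <- s$grf_right$values[(w$start_frame + 1):w$end_frame, "grf_z"] +
        s$grf_left$values[(w$start_frame + 1):w$end_frame, "grf_z"]
      max(seg) / bw
    }, numeric(1))
  }))
  expect_true(all(ratios > 1.8 & ratios < 4.2))
})

test_that("the full pipeline recovers every manifest ground truth", {
  spec <- small_spec(seed = 17, n_subjects = 3, jumps = 4)
  cohort <- simulate_cohort(spec)
  for (s in cohort$sessions) {
    pr <- process_session(s)
    expect_identical(pr$sync$lag_frames, as.integer(s$truth$offset_frames))
    tw <- s$truth$contact_windows
    expect_length(pr$phases, nrow(tw))
    for (j in seq_along(pr$phases)) {
      expect_lte(abs(pr$phases[[j]]$start_frame - tw$start_frame[j]), 1L)
      expect_lte(abs(pr$phases[[j]]$end_frame - tw$end_frame[j]), 1L)
    }
  }
})
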