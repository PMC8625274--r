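#' Synthetic drop-jump cohort specification
#'
#' Defines the study conditions emulated by the simulator: an 11-subject
#' cohort performing up to 10 vertical drop jumps each, recorded by three
#' 6-channel IMUs at 128 Hz, an optical reference marker at 100 Hz, and two
#' per-foot force plates at 200 Hz. Sessions start with the quasi-periodic
#' hand-shake synchronization trigger; the optical and inertial clocks
#' differ by a drawn integer offset. The six kinetic targets are produced
#' from the IMU channels by a known nonlinear delayed mapping (see
#' [true_mapping()]), so every pipeline stage can be validated against
#' ground truth.
#'
#' @param n_subjects Number of subjects (default 11).
#' @param jumps_per_subject Jumps per recording session (default 10).
#' @param mass_range_kg Body-mass range sampled per subject (default
#'   `c(50, 85)` kg).
#' @param contact_range_s First-landing contact duration range (default
#'   `c(0.25, 0.45)` s).
#' @param offset_range_frames Optical-vs-IMU clock offset range, in integer
#'   frames at 128 Hz (default `c(-500, 500)`).
#' @param spike_cycles Hand-shake oscillation cycles (default 5).
#' @param spike_freq_hz Hand-shake frequency (default 1 Hz).
#' @param imu_noise_sd IMU channel noise SD, sensor units (default 0.02).
#' @param target_noise_sd Target noise SD in normalized units (N/kg,
#'   N·m/kg); default 0.05.
#' @param grf_noise_sd_n Force-plate noise SD in newtons (default 1 N, a
#'   typical laboratory plate noise floor; the 10 N contact threshold then
#'   sits far outside the unloaded noise band).
#' @param mapping Mapping parameters from [default_mapping()].
#' @param misspecify Add a small delay-3 term absent from the default NARX
#'   delay set, for robustness studies (default `FALSE`).
#' @param seed Integer master seed.
#'
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_subjects = 11L, jumps_per_subject = 10L,
                        mass_range_kg = c(50, 85),
                        contact_range_s = c(0.25, 0.45),
                        offset_range_frames = c(-500L, 500L),
                        spike_cycles = 5L, spike_freq_hz = 1,
                        imu_noise_sd = 0.02, target_noise_sd = 0.05,
                        grf_noise_sd_n = 1,
                        mapping = default_mapping(),
                        misspecify = FALSE, seed = 1L) {
  stopifnot(n_subjects >= 1L, jumps_per_subject >= 1L,
            mass_range_kg[1] > 0, diff(mass_range_kg) >= 0,
            contact_range_s[1] > 0, diff(contact_range_s) >= 0,
            spike_cycles >= 1L, spike_freq_hz > 0)
  if (misspecify) mapping <- .misspecify_mapping(mapping)
  structure(
    list(n_subjects = as.integer(n_subjects),
         jumps_per_subject = as.integer(jumps_per_subject),
         mass_range_kg = mass_range_kg, contact_range_s = contact_range_s,
         offset_range_frames = as.integer(offset_range_frames),
         spike_cycles = as.integer(spike_cycles),
         spike_freq_hz = spike_freq_hz,
         imu_noise_sd = imu_noise_sd, target_noise_sd = target_noise_sd,
         grf_noise_sd_n = grf_noise_sd_n,
         mapping = mapping, misspecify = isTRUE(misspecify),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

.GRAVITY <- 9.81
.IMU_RATE <- 128
.OPT_RATE <- 100
.GRF_RATE <- 200

# IMU channel bookkeeping: 18 channels in canonical schema order; channel 6
# (sa_acc_z) is the vertical master channel that carries gravity, the sync
# spike and the landing pulse.
.ACC_Z_CHANNELS <- c(6L, 12L, 18L)
.MASTER_VERTICAL <- 6L

#' Ground-truth IMU-to-kinetics mapping parameters
#'
#' The six targets are generated from the 18 IMU channels `u` as
#' `y_j(t) = sum_s W1[j,s] * tanh(alpha * u_s(t-1)) + W2[j,s] * u_s(t-2) + c_j`
#' (delays in 128 Hz frames), deliberately using only delays 1 and 2 so the
#' default NARX delay set is well-specified. The vertical-GRF row is purely
#' linear with a single weight on the sacrum vertical accelerometer, which
#' itself carries the landing force pulse scaled by `1/mass` -- the synthetic
#' counterpart of Newton's second law linking centre-of-mass acceleration to
#' the total ground reaction force. Weights are fixed deterministic values
#' scaled per channel family (gyroscope vs accelerometer) so each target has
#' a physiologically plausible magnitude.
#'
#' @return A list with `W1`, `W2` (6 x 18), `alpha`, `c` (length 6), `W3`
#'   (6 x 18, zero unless misspecified).
#' @export
default_mapping <- function() {
  .with_seed(1123581L, function() {
    gyro <- c(1:3, 7:9, 13:15)
    acc <- setdiff(1:18, gyro)
    W1 <- matrix(0, 6, 18)
    W2 <- matrix(0, 6, 18)
    for (j in 1:5) {
      scale <- if (j >= 4) 2 else 1   # horizontal GRFs span a larger range
      W1[j, gyro] <- stats::rnorm(length(gyro), 0, 0.25) * scale
      W1[j, acc] <- stats::rnorm(length(acc), 0, 0.10) * scale
      W2[j, gyro] <- stats::rnorm(length(gyro), 0, 0.0015) * scale
      W2[j, acc] <- stats::rnorm(length(acc), 0, 0.015) * scale
    }
    # vertical GRF: exact linear pick-off of the sacrum vertical channel
    W1[6, ] <- 0
    W2[6, ] <- 0
    W2[6, .MASTER_VERTICAL] <- 0.5
    cc <- c(stats::rnorm(5, 0, 0.05), -0.5 * .GRAVITY)
    dimnames(W1) <- dimnames(W2) <- NULL
    list(W1 = W1, W2 = W2, alpha = 0.002, c = cc, W3 = matrix(0, 6, 18))
  })
}

.misspecify_mapping <- function(mapping) {
  mapping$W3 <- .with_seed(3141592L, function() {
    matrix(stats::rnorm(6 * 18, 0, 0.003), 6, 18)
  })
  mapping$W3[6, ] <- 0
  mapping
}

#' Evaluate the ground-truth mapping on a delayed input history
#'
#' Deterministic, noise-free evaluation of the generator's mapping for one
#' time step. `u_history` must provide the input vectors at `t-1` and `t-2`
#' (rows 1 and 2; a third row `t-3` is required when the mapping carries a
#' misspecification term).
#'
#' @param u_history Matrix with 18 columns; row `d` is `u(t-d)`.
#' @param mapping Parameters from [default_mapping()].
#' @return Named numeric vector of the 6 target values.
#' @export
true_mapping <- function(u_history, mapping = default_mapping()) {
  if (is.null(dim(u_history))) {
    stop("u_history must be a matrix with one row per delay", call. = FALSE)
  }
  needs <- if (any(mapping$W3 != 0)) 3L else 2L
  if (nrow(u_history) < needs || ncol(u_history) != 18L) {
    stop("u_history must provide at least ", needs, " rows of 18 channels",
         call. = FALSE)
  }
  y <- mapping$W1 %*% tanh(mapping$alpha * u_history[1, ]) +
    mapping$W2 %*% u_history[2, ] + mapping$c
  if (any(mapping$W3 != 0)) y <- y + mapping$W3 %*% u_history[3, ]
  stats::setNames(as.numeric(y), vdj_target_columns())
}

# Mapping applied along a sampled series: U is L x 18; returns L x 6 with
# NA rows while the delay lines are unfilled.
.true_mapping_series <- function(U, mapping) {
  L <- nrow(U)
  max_d <- if (any(mapping$W3 != 0)) 3L else 2L
  Y <- matrix(NA_real_, L, 6L)
  if (L <= max_d) return(Y)
  rows <- (max_d + 1L):L
  Yv <- tanh(mapping$alpha * U[rows - 1L, , drop = FALSE]) %*% t(mapping$W1) +
    U[rows - 2L, , drop = FALSE] %*% t(mapping$W2)
  if (max_d == 3L) Yv <- Yv + U[rows - 3L, , drop = FALSE] %*% t(mapping$W3)
  Y[rows, ] <- sweep(Yv, 2L, mapping$c, "+")
  colnames(Y) <- vdj_target_columns()
  Y
}

# C1 smoothstep ramp-in/ramp-out envelope on x in [0, 1], edge width w.
.taper <- function(x, w) {
  s <- function(z) {
    z <- pmin(pmax(z, 0), 1)
    z * z * (3 - 2 * z)
  }
  s(x / w) * s((1 - x) / w)
}

# Two-peak first-landing pulse shape on x in [0, 1], peak value 1.
.pulse_shape <- local({
  raw <- function(x) {
    out <- numeric(length(x))
    inside <- x > 0 & x < 1
    xi <- x[inside]
    out[inside] <- .taper(xi, 0.12) *
      (0.75 * exp(-((xi - 0.30) / 0.17)^2) + 0.65 * exp(-((xi - 0.72) / 0.17)^2))
    out
  }
  peak <- max(raw(seq(0, 1, length.out = 2001)))
  function(x) raw(x) / peak
})

# Single-peak second-contact shape.
.pulse2_shape <- function(x) {
  out <- numeric(length(x))
  inside <- x > 0 & x < 1
  xi <- x[inside]
  out[inside] <- .taper(xi, 0.08) * exp(-((xi - 0.5) / 0.22)^2)
  out
}

# Smooth transient shape for generic IMU channels (vanishes at both ends).
.imu_shape <- function(x, coef) {
  out <- numeric(length(x))
  inside <- x > 0 & x < 1
  xi <- x[inside]
  out[inside] <- coef[1] * sin(pi * xi)^2 + coef[2] * sin(2 * pi * xi) +
    coef[3] * sin(3 * pi * xi)
  out
}

# Cohort-level channel profile: transient amplitude and shape coefficients
# per channel, identical for every session of a cohort.
.channel_profile <- function(spec) {
  .with_seed(spec$seed %% 1000000L * 31L + 7L, function() {
    gyro <- c(1:3, 7:9, 13:15)
    amp <- numeric(18)
    amp[gyro] <- stats::runif(length(gyro), 100, 350)       # deg/s
    amp[setdiff(1:18, gyro)] <- stats::runif(9, 5, 25)      # m/s^2
    amp[.MASTER_VERTICAL] <- 0                              # reserved channel
    coefs <- cbind(stats::runif(18, 0.5, 1) * sample(c(-1, 1), 18, TRUE),
                   stats::runif(18, -0.6, 0.6),
                   stats::runif(18, -0.4, 0.4))
    base_f <- matrix(stats::runif(18 * 3, 0.2, 1.5), 18, 3)
    list(amp = amp, coefs = coefs, base_f = base_f)
  })
}

# Build the continuous-time session model for one subject: closures for the
# 18 clean IMU channels, the total vertical force pulse, and the session
# timeline. Everything downstream (streams at any rate, target series) is
# sampled from these, which keeps all modalities mutually consistent.
.session_model <- function(spec, subject) {
  profile <- .channel_profile(spec)
  subject_seed <- (as.numeric(spec$seed) * 97 + subject * 1009) %% 2147483647
  draw <- .with_seed(subject_seed, function() {
    nj <- spec$jumps_per_subject
    list(
      mass = stats::runif(1, spec$mass_range_kg[1], spec$mass_range_kg[2]),
      offset = sample(seq(spec$offset_range_frames[1],
                          spec$offset_range_frames[2]), 1L),
      d = stats::runif(nj, spec$contact_range_s[1], spec$contact_range_s[2]),
      kappa = stats::runif(nj, 2, 4),
      jitter = matrix(stats::runif(nj * 18, 0.85, 1.15), nj, 18),
      base_amp = matrix(stats::rnorm(18 * 3, 0, 1), 18, 3),
      base_ph = matrix(stats::runif(18 * 3, 0, 2 * pi), 18, 3),
      noise_seed = sample.int(2147483646L, 1L)
    )
  })

  f_sp <- spec$spike_freq_hz
  t_spike <- 4.2
  spike_len <- spec$spike_cycles / f_sp
  t1 <- t_spike + spike_len + 2.0
  starts <- numeric(spec$jumps_per_subject)   # first-landing contact starts
  t <- t1
  for (j in seq_len(spec$jumps_per_subject)) {
    t <- t + 0.40                 # box drop flight
    starts[j] <- t
    t <- t + draw$d[j] + 0.35 +   # contact, jump flight
      0.40 + 0.55                 # second landing, reposition
  }
  duration <- t + 5.0             # tail covers the largest negative offset

  mass <- draw$mass
  spike_fun <- function(tau) {
    x <- (tau - t_spike) / spike_len
    amp <- 0.1 * (2 * pi * f_sp)^2            # 0.1 m hand-shake amplitude
    -amp * .taper(x, 0.1) * sin(2 * pi * f_sp * (tau - t_spike)) *
      as.numeric(x > 0 & x < 1)
  }
  marker_fun <- function(tau) {               # optical marker height, mm
    x <- (tau - t_spike) / spike_len
    1000 + 100 * .taper(x, 0.1) * sin(2 * pi * f_sp * (tau - t_spike)) *
      as.numeric(x > 0 & x < 1)
  }
  pulse_fun <- function(tau) {                # total vertical GRF, N
    out <- numeric(length(tau))
    for (j in seq_along(starts)) {
      out <- out + mass * .GRAVITY * draw$kappa[j] *
        .pulse_shape((tau - starts[j]) / draw$d[j])
      s2 <- starts[j] + draw$d[j] + 0.35
      out <- out + mass * .GRAVITY * 2.5 * .pulse2_shape((tau - s2) / 0.40)
    }
    out
  }
  u_fun <- function(tau) {                    # clean IMU channels, M x 18
    U <- matrix(0, length(tau), 18L)
    for (s in 1:18) {
      if (s == .MASTER_VERTICAL) {
        U[, s] <- .GRAVITY + spike_fun(tau) + pulse_fun(tau + 2 / .IMU_RATE) / mass
        next
      }
      b <- numeric(length(tau))
      for (k in 1:3) {
        b <- b + 0.05 * profile$amp[s] * draw$base_amp[s, k] / 3 *
          sin(2 * pi * profile$base_f[s, k] * tau + draw$base_ph[s, k])
      }
      for (j in seq_along(starts)) {
        b <- b + profile$amp[s] * draw$jitter[j, s] *
          .imu_shape((tau - starts[j]) / draw$d[j], profile$coefs[s, ])
      }
      if (s %in% .ACC_Z_CHANNELS) b <- b + .GRAVITY
      U[, s] <- b
    }
    U
  }
  y_fun <- function(tau) {                    # clean targets from the mapping
    m <- spec$mapping
    Y <- tanh(m$alpha * u_fun(tau - 1 / .IMU_RATE)) %*% t(m$W1) +
      u_fun(tau - 2 / .IMU_RATE) %*% t(m$W2)
    if (any(m$W3 != 0)) Y <- Y + u_fun(tau - 3 / .IMU_RATE) %*% t(m$W3)
    sweep(Y, 2L, m$c, "+")
  }

  list(mass = mass, offset = draw$offset, contact_starts = starts,
       contact_durations = draw$d, kappa = draw$kappa,
       duration = duration, noise_seed = draw$noise_seed,
       spike_window_s = c(t_spike, t_spike + spike_len),
       marker_fun = marker_fun, pulse_fun = pulse_fun,
       u_fun = u_fun, y_fun = y_fun)
}

#' Simulate one drop-jump recording session
#'
#' Generates all streams of one subject's session on two unsynchronized
#' clocks: the inertial streams (three 6-channel IMUs at 128 Hz) on the IMU
#' network clock, and the optical marker (100 Hz), per-foot ground reaction
#' forces (200 Hz, newtons) and knee moments (128 Hz, N·m/kg) on the optical
#' clock, which starts `offset_frames / 128` s after the IMU clock. The
#' session opens with the hand-shake synchronization trigger, visible as a
#' marker oscillation and (sign-inverted) in the sacrum vertical
#' accelerometer. Noise is added after all ground-truth bookkeeping.
#'
#' @param spec A [cohort_spec()].
#' @param subject Subject index (1-based).
#'
#' @return A `synthetic_session` list: `subject_id`, `mass_kg`, streams
#'   (`imu` = list `sa`, `rt`, `rl`; `marker`; `grf_right`; `grf_left`;
#'   `moments`), and `truth` (offset, contact windows on the optical clock,
#'   clean sampled IMU matrix and clean target series at 128 Hz, mapping).
#' @export
simulate_session <- function(spec, subject) {
  stopifnot(inherits(spec, "cohort_spec"))
  model <- .session_model(spec, subject)
  mass <- model$mass
  s0 <- model$offset / .IMU_RATE          # optical start on the IMU clock
  Tdur <- model$duration
  grf_sd <- spec$grf_noise_sd_n

  imu_t <- (0:(floor(Tdur * .IMU_RATE) - 1L)) / .IMU_RATE
  opt128_t <- s0 + (0:(floor(Tdur * .IMU_RATE) - 1L)) / .IMU_RATE
  opt100_t <- s0 + (0:(floor(Tdur * .OPT_RATE) - 1L)) / .OPT_RATE
  opt200_t <- s0 + (0:(floor(Tdur * .GRF_RATE) - 1L)) / .GRF_RATE

  U_clean <- model$u_fun(imu_t)
  Y_clean <- .true_mapping_series(U_clean, spec$mapping)
  moments_clean <- model$y_fun(opt128_t)[, 1:3, drop = FALSE]
  grf_xy_clean <- mass * model$y_fun(opt200_t)[, 4:5, drop = FALSE]
  pulse200 <- model$pulse_fun(opt200_t)
  marker_clean <- model$marker_fun(opt100_t)

  # ground-truth contact windows: threshold crossing of the clean summed
  # vertical GRF at the force-plate rate, first landing of each pair
  above <- pulse200 > 10
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  w <- which(runs$values)
  first <- seq(1L, length(w), by = 2L)
  windows <- tibble::tibble(
    jump_id = seq_along(first),
    start_frame = starts[w[first]] - 1L,
    end_frame = ends[w[first]],
    rate_hz = .GRF_RATE,
    start_s = (starts[w[first]] - 1L) / .GRF_RATE,   # optical clock
    end_s = ends[w[first]] / .GRF_RATE,
    duration_s = (ends[w[first]] - starts[w[first]] + 1L) / .GRF_RATE
  )

  labels_imu <- .imu_channel_labels()
  noise <- .with_seed(model$noise_seed, function() {
    list(
      imu = matrix(stats::rnorm(length(U_clean), 0, spec$imu_noise_sd),
                   nrow(U_clean), ncol(U_clean)),
      moments = matrix(stats::rnorm(length(moments_clean), 0,
                                    spec$target_noise_sd),
                       nrow(moments_clean), 3L),
      grf_r = matrix(stats::rnorm(3L * length(pulse200), 0, grf_sd),
                     length(pulse200), 3L),
      grf_l = matrix(stats::rnorm(3L * length(pulse200), 0, grf_sd),
                     length(pulse200), 3L),
      marker = stats::rnorm(length(marker_clean), 0, 0.5)
    )
  })

  U_noisy <- U_clean + noise$imu
  imu <- list(
    sa = sampled_signal(U_noisy[, 1:6], labels_imu, .IMU_RATE, 0),
    rt = sampled_signal(U_noisy[, 7:12], labels_imu, .IMU_RATE, 0),
    rl = sampled_signal(U_noisy[, 13:18], labels_imu, .IMU_RATE, 0)
  )
  grf_labels <- c("grf_x", "grf_y", "grf_z")
  grf_right <- sampled_signal(
    cbind(grf_xy_clean, pulse200 / 2) + noise$grf_r, grf_labels, .GRF_RATE, 0)
  grf_left <- sampled_signal(
    cbind(-0.8 * grf_xy_clean[, 1], 0.9 * grf_xy_clean[, 2], pulse200 / 2) +
      noise$grf_l, grf_labels, .GRF_RATE, 0)
  moments <- sampled_signal(moments_clean + noise$moments,
                            c("knee_fe", "knee_aa", "knee_r"), .IMU_RATE, 0)
  marker <- sampled_signal(marker_clean + noise$marker, "marker_y",
                           .OPT_RATE, 0)

  structure(
    list(subject_id = sprintf("S%02d", subject), mass_kg = mass,
         imu = imu, marker = marker, grf_right = grf_right,
         grf_left = grf_left, moments = moments,
         truth = list(offset_frames = model$offset,
                      contact_windows = windows,
                      mass_kg = mass,
                      kappa = model$kappa,
                      contact_durations_s = model$contact_durations,
                      u_clean = U_clean, y_clean = Y_clean,
                      mapping = spec$mapping)),
    class = "synthetic_session"
  )
}

#' Simulate a full cohort
#'
#' @param spec A [cohort_spec()].
#' @return A list with `sessions` (list of [simulate_session()] results) and
#'   `manifest`: per-subject ground truth (mass, clock offset, contact
#'   windows) suitable for JSON serialization and test assertions.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sessions <- lapply(seq_len(spec$n_subjects), function(i) {
    simulate_session(spec, i)
  })
  manifest <- list(
    seed = spec$seed,
    n_subjects = spec$n_subjects,
    jumps_per_subject = spec$jumps_per_subject,
    target_noise_sd = spec$target_noise_sd,
    subjects = lapply(sessions, function(s) {
      list(subject_id = s$subject_id,
           mass_kg = s$mass_kg,
           offset_frames = s$truth$offset_frames,
           contact_windows = as.data.frame(
             s$truth$contact_windows[, c("jump_id", "start_s", "end_s",
                                         "duration_s")]))
    })
  )
  list(sessions = sessions, manifest = manifest)
}
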