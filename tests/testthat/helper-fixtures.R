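# Shared fixture builders. Everything is generated in code at test time.

# single-channel sine stream
sine_signal <- function(freq_hz, rate_hz, duration_s, amp = 1, t0_s = 0,
                        label = "x") {
  t <- seq(0, duration_s - 1 / rate_hz, by = 1 / rate_hz)
  sampled_signal(amp * sin(2 * pi * freq_hz * t), label, rate_hz, t0_s)
}

# smooth band-limited random signal (for correlation/resampling tests)
smooth_noise <- function(n, rate_hz = 128, cutoff_hz = 8, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n + 400)
  bf <- signal::butter(4, cutoff_hz / (rate_hz / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))[201:(200 + n)]
}

# steady-state amplitude of a filtered sine at a known frequency, by DFT
# projection over an integer number of cycles in the middle of the record
# (avoids both transients and peak-sampling bias)
steady_amplitude <- function(x, freq_hz, rate_hz) {
  n <- length(x)
  start <- floor(n / 3)
  ncyc <- floor((n / 3) / rate_hz * freq_hz)
  len <- round(ncyc * rate_hz / freq_hz)
  idx <- start + seq_len(len)
  t <- (idx - 1) / rate_hz
  2 * Mod(mean(x[idx] * exp(-2i * pi * freq_hz * t)))
}

# canonical-schema training table from per-jump predictor/target matrices;
# jumps is a list of list(U = L x 18, Y = L x 6)
make_dataset <- function(subjects) {
  blocks <- list()
  for (sid in names(subjects)) {
    for (j in seq_along(subjects[[sid]])) {
      U <- subjects[[sid]][[j]]$U
      Y <- subjects[[sid]][[j]]$Y
      L <- nrow(U)
      block <- tibble::as_tibble(cbind(U, Y), .name_repair = "minimal")
      names(block) <- vdj_schema()[-1]
      blocks[[length(blocks) + 1L]] <- tibble::add_column(
        block, subject_id = sid, jump_id = j, frame_index = seq_len(L),
        .before = 1L)
    }
  }
  concatenate_subjects(blocks)
}

# linear vector-ARX cohort: y(t) = A1 y(t-1) + A2 y(t-2) + B1 u(t-1) +
# B2 u(t-2) + c + noise, one known ground-truth parameter set shared by all
# subjects. Exactly representable by a linear NARX with delays {1, 2}.
arx_system <- function(seed = 42) {
  set.seed(seed)
  list(A1 = diag(0.35, 6) + matrix(rnorm(36, 0, 0.02), 6),
       A2 = diag(-0.15, 6),
       B1 = matrix(rnorm(6 * 18, 0, 0.12), 6, 18),
       B2 = matrix(rnorm(6 * 18, 0, 0.08), 6, 18),
       c0 = rnorm(6, 0, 0.1))
}

arx_dataset <- function(n_subjects = 4, jumps = 3, L = 40, noise_sd = 0,
                        sys = arx_system(), seed = 7) {
  set.seed(seed)
  subjects <- list()
  for (s in seq_len(n_subjects)) {
    sj <- list()
    for (j in seq_len(jumps)) {
      U <- matrix(rnorm(L * 18), L, 18)
      Y <- matrix(0, L, 6)
      Y[1, ] <- rnorm(6, 0, 0.1)
      Y[2, ] <- rnorm(6, 0, 0.1)
      for (t in 3:L) {
        Y[t, ] <- sys$A1 %*% Y[t - 1, ] + sys$A2 %*% Y[t - 2, ] +
          sys$B1 %*% U[t - 1, ] + sys$B2 %*% U[t - 2, ] + sys$c0 +
          rnorm(6, 0, noise_sd)
      }
      sj[[j]] <- list(U = U, Y = Y)
    }
    subjects[[sprintf("A%02d", s)]] <- sj
  }
  make_dataset(subjects)
}

# small fast NARX configuration for tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(hidden_sizes = 8L, epochs = 50L, regularization_gamma = 1,
         seed = 1L),
    list(...))
  do.call(narx_config, args)
}

# a small but complete synthetic session (cheap to simulate)
small_spec <- function(seed = 5, n_subjects = 2, jumps = 3, ...) {
  cohort_spec(n_subjects = n_subjects, jumps_per_subject = jumps,
              seed = seed, ...)
}
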