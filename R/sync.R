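#' Locate the quasi-periodic synchronization spike train
#'
#' Each recording session starts with an operator shaking the master sensor
#' (with its attached reflective marker) up and down several times, which
#' plants a quasi-periodic oscillation near the start of both the optical and
#' the inertial records. This function automates the manual cut of that
#' trigger window: the signal is band-passed to `band_hz`, an energy envelope
#' is formed by a moving RMS, and the earliest contiguous run whose envelope
#' stays above a descending threshold grid for at least `min_cycles`
#' oscillations (at the fastest in-band frequency) is returned. A detected
#' window must also stand clearly above the record's quiet background
#' energy; otherwise detection is declared failed and the whole record is
#' returned with `detected = FALSE`.
#'
#' @param signal Single-channel [sampled_signal()].
#' @param min_cycles Minimum number of oscillation cycles (default 5).
#' @param band_hz Two-element frequency band (Hz) of the hand-shake
#'   oscillation, default `c(0.5, 3)`.
#'
#' @return A list with `start`, `end` (half-open 0-based frame window) and
#'   `detected` (logical).
#' @export
find_spike_window <- function(signal, min_cycles = 5L, band_hz = c(0.5, 3)) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (ncol(signal$values) != 1L) {
    stop("find_spike_window expects a single-channel signal", call. = FALSE)
  }
  n <- n_frames(signal)
  rate <- signal$rate_hz
  whole <- list(start = 0L, end = n, detected = FALSE)
  if (band_hz[2] >= rate / 2 || n < 4L * rate / band_hz[1]) return(whole)

  x <- signal$values[, 1] - mean(signal$values[, 1])
  bf <- signal::butter(2, band_hz / (rate / 2), type = "pass")
  xb <- signal::filtfilt(bf, x)

  smooth_frames <- max(3L, round(rate / band_hz[2]))
  env <- sqrt(stats::filter(xb^2, rep(1 / smooth_frames, smooth_frames),
                            sides = 2))
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  if (max(env) <= 0) return(whole)

  min_len <- ceiling(min_cycles / band_hz[2] * rate)
  pad <- smooth_frames %/% 2L + smooth_frames
  # jump landings later in the record can carry more band energy than the
  # trigger burst, but the trigger always comes first: collect sufficiently
  # long runs over a descending threshold grid and keep the earliest one
  # that stands clearly above the background energy
  best <- NULL
  for (frac in c(0.5, 0.35, 0.25, 0.15, 0.1, 0.07, 0.05)) {
    above <- env > frac * max(env)
    runs <- rle(above)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in which(runs$values & runs$lengths >= min_len)) {
      # expand by the envelope smoothing window so the taper at the burst
      # edges is not clipped off
      s <- max(0L, starts[i] - 1L - pad)
      e <- min(n, ends[i] + pad)
      if (mean(env[(s + 1L):e]) < 3 * (stats::quantile(env, 0.25) + 1e-12)) next
      if (is.null(best) || s < best$start) {
        best <- list(start = as.integer(s), end = as.integer(e),
                     detected = TRUE)
      }
    }
  }
  if (is.null(best)) whole else best
}

#' Estimate the clock offset between two streams by cross-correlation
#'
#' Scans integer frame lags and picks the one maximizing the normalized
#' cross-correlation (Pearson correlation over the overlapping frames, i.e.
#' mean-removed and variance-normalized). Ties are broken toward the smallest
#' absolute lag. The two inputs may be crops of longer records: their `t0_s`
#' values are taken into account, so the returned lag is always the offset
#' between the two *full* streams' clocks. A positive lag means `other`
#' records any given event `lag_s` seconds later than `reference`.
#'
#' The optical marker trajectory is positive upwards while the master-sensor
#' vertical axis is positive downwards; set `invert_other = TRUE` to negate
#' `other` before correlating so the correlation peak keeps an interpretable
#' sign.
#'
#' @param reference,other Single-channel [sampled_signal()] objects at the
#'   same rate, each with at least 32 frames.
#' @param invert_other Negate `other` before correlating (default `FALSE`).
#' @param max_lag Maximum |value lag| scanned, in frames; default half the
#'   shorter signal.
#'
#' @return A `sync_result` list: `lag_frames`, `lag_s`, `peak_correlation`,
#'   `window_ref`, `window_other` (the frame windows actually correlated, on
#'   each stream's own frame axis).
#' @export
estimate_delay <- function(reference, other, invert_other = FALSE, max_lag = NULL) {
  stopifnot(inherits(reference, "sampled_signal"),
            inherits(other, "sampled_signal"))
  if (ncol(reference$values) != 1L || ncol(other$values) != 1L) {
    stop("estimate_delay expects single-channel signals", call. = FALSE)
  }
  if (abs(reference$rate_hz - other$rate_hz) > 1e-9) {
    stop("rate mismatch: resample both streams to a common rate first",
         call. = FALSE)
  }
  if (n_frames(reference) < 32L || n_frames(other) < 32L) {
    stop("signals must have at least 32 frames", call. = FALSE)
  }
  rate <- reference$rate_hz
  x <- as.numeric(reference$values[, 1])
  y <- as.numeric(other$values[, 1])
  if (invert_other) y <- -y
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: cross-correlation undefined for zero variance",
         call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  if (is.null(max_lag)) max_lag <- floor(min(nx, ny) / 2)
  min_overlap <- 16L

  lags <- -max_lag:max_lag
  lags <- lags[order(abs(lags))]   # smallest |lag| first -> tie break
  best_r <- -Inf
  best_lag <- 0L
  for (k in lags) {
    # correlate x[i] with y[i + k]
    i0 <- max(1L, 1L - k); i1 <- min(nx, ny - k)
    if (i1 - i0 + 1L < min_overlap) next
    xs <- x[i0:i1]; ys <- y[(i0 + k):(i1 + k)]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) next
    r <- stats::cor(xs, ys)
    if (r > best_r + 1e-12) {
      best_r <- r
      best_lag <- k
    }
  }
  t0_term <- round((other$t0_s - reference$t0_s) * rate)
  lag_frames <- as.integer(best_lag + t0_term)
  structure(
    list(lag_frames = lag_frames,
         lag_s = lag_frames / rate,
         peak_correlation = best_r,
         window_ref = c(start = 0L, end = nx),
         window_other = c(start = 0L, end = ny),
         rate_hz = rate),
    class = "sync_result"
  )
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf("<sync_result> lag = %d frames (%.4f s) @ %g Hz, peak r = %.4f\n",
              x$lag_frames, x$lag_s, x$rate_hz, x$peak_correlation))
  invisible(x)
}

#' Apply an estimated clock offset to a set of streams
#'
#' Shifts the `t0_s` of the selected streams by `-lag_s`, placing them on the
#' reference stream's clock. Sample values are never altered. Because all
#' IMU units share one network clock, a single offset (estimated from the
#' master sensor) aligns every inertial stream at once.
#'
#' @param streams List of [sampled_signal()] objects.
#' @param result A `sync_result` from [estimate_delay()].
#' @param apply_to Indices or names of the streams to shift (default all).
#'
#' @return The list of streams with shifted `t0_s`.
#' @export
align_streams <- function(streams, result, apply_to = seq_along(streams)) {
  stopifnot(inherits(result, "sync_result"))
  for (i in apply_to) {
    streams[[i]]$t0_s <- streams[[i]]$t0_s - result$lag_s
  }
  streams
}

#' Full synchronization of an optical and an inertial trigger pair
#'
#' Convenience wrapper implementing the whole synchronization recipe: the
#' marker vertical trajectory is resampled to the IMU working rate, the
#' master-sensor vertical acceleration has gravity removed and is low-pass
#' filtered (4th order, `sync_cutoff_hz`), spike windows are detected on both
#' (or taken from explicit overrides), and the cut windows are
#' cross-correlated with polarity inversion.
#'
#' @param marker_vertical Single-channel marker trajectory (any rate).
#' @param master_accel_vertical Single-channel master-sensor vertical
#'   acceleration at the working rate.
#' @param sync_cutoff_hz Low-pass cutoff for the accelerometer (default 10).
#' @param window_ref,window_other Optional manual half-open frame windows
#'   (on the resampled marker / the accelerometer) overriding detection.
#' @param min_cycles,band_hz Passed to [find_spike_window()].
#'
#' @return A `sync_result`; `window_ref`/`window_other` report the windows
#'   actually correlated and an attribute `detected` records whether both
#'   auto-detections succeeded.
#' @export
sync_streams <- function(marker_vertical, master_accel_vertical,
                         sync_cutoff_hz = 10, window_ref = NULL,
                         window_other = NULL, min_cycles = 5L,
                         band_hz = c(0.5, 3)) {
  rate <- master_accel_vertical$rate_hz
  ref <- resample_uniform(marker_vertical, rate)
  acc <- lowpass_butterworth(remove_gravity(master_accel_vertical),
                             cutoff_hz = sync_cutoff_hz, order = 4L)
  if (is.null(window_ref)) {
    wr <- find_spike_window(ref, min_cycles = min_cycles, band_hz = band_hz)
  } else {
    wr <- list(start = window_ref[[1]], end = window_ref[[2]], detected = TRUE)
  }
  if (is.null(window_other)) {
    wo <- find_spike_window(acc, min_cycles = min_cycles, band_hz = band_hz)
  } else {
    wo <- list(start = window_other[[1]], end = window_other[[2]], detected = TRUE)
  }
  if (!wr$detected || !wo$detected) {
    # correlate whole records on both sides so the lag search space stays
    # symmetric when only one spike window was found
    wr <- list(start = 0L, end = n_frames(ref), detected = wr$detected)
    wo <- list(start = 0L, end = n_frames(acc), detected = wo$detected)
  }
  res <- estimate_delay(crop_frames(ref, wr$start, wr$end),
                        crop_frames(acc, wo$start, wo$end),
                        invert_other = TRUE)
  res$window_ref <- c(start = wr$start, end = wr$end)
  res$window_other <- c(start = wo$start, end = wo$end)
  attr(res, "detected") <- wr$detected && wo$detected
  res
}
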