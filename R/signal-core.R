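#' Uniformly sampled multi-channel signal
#'
#' `sampled_signal()` is the universal carrier for every stream in the
#' pipeline: IMU accelerometer/gyroscope channels, the optical reference
#' marker trajectory, force-plate ground reaction forces, and knee joint
#' moments. Frames are equally spaced at `1 / rate_hz` seconds and the first
#' frame sits at `t0_s` on a shared trial clock, so streams recorded by
#' different devices can be placed on one time axis after synchronization.
#'
#' @param values Numeric matrix (frames x channels), or a vector for a
#'   single-channel stream. Missing values are rejected: gaps are an
#'   ingestion error, not a signal state.
#' @param labels Character vector of channel names, one per column.
#' @param rate_hz Sampling frequency in Hz (> 0).
#' @param t0_s Time of the first frame on the trial clock, in seconds.
#'
#' @return An object of class `sampled_signal`.
#' @export
#' @examples
#' s <- sampled_signal(sin(2 * pi * 5 * (0:127) / 128), "acc_z", 128)
#' n_frames(s)
sampled_signal <- function(values, labels, rate_hz, t0_s = 0) {
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) {
    stop("number of labels (", length(labels), ") must equal number of channels (",
         ncol(values), ")", call. = FALSE)
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) || rate_hz <= 0) {
    stop("rate_hz must be a single positive number", call. = FALSE)
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop("signal values contain missing or non-finite entries", call. = FALSE)
  }
  colnames(values) <- labels
  structure(
    list(values = values, labels = labels, rate_hz = as.numeric(rate_hz),
         t0_s = as.numeric(t0_s)),
    class = "sampled_signal"
  )
}

#' @export
print.sampled_signal <- function(x, ...) {
  cat(sprintf("<sampled_signal> %d frames x %d channels @ %g Hz, t0 = %g s\n",
              nrow(x$values), ncol(x$values), x$rate_hz, x$t0_s))
  cat("channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Number of frames in a signal
#' @param signal A [sampled_signal()].
#' @return Integer frame count.
#' @export
n_frames <- function(signal) {
  stopifnot(inherits(signal, "sampled_signal"))
  nrow(signal$values)
}

#' Frame times on the trial clock
#' @param signal A [sampled_signal()].
#' @return Numeric vector of times (s), `t0_s + (0:(n-1)) / rate_hz`.
#' @export
signal_times <- function(signal) {
  stopifnot(inherits(signal, "sampled_signal"))
  signal$t0_s + (seq_len(n_frames(signal)) - 1L) / signal$rate_hz
}

#' Select a single channel as a new signal
#' @param signal A [sampled_signal()].
#' @param label Channel name to extract.
#' @return A single-channel [sampled_signal()].
#' @export
signal_channel <- function(signal, label) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (!label %in% signal$labels) {
    stop("no channel named '", label, "'", call. = FALSE)
  }
  sampled_signal(signal$values[, label, drop = FALSE], label,
                 signal$rate_hz, signal$t0_s)
}

#' Zero-phase (or single-pass) low-pass Butterworth filter
#'
#' Applies a low-pass Butterworth filter of the given order to every channel
#' independently. With `zero_phase = TRUE` (default) the filter runs forward
#' then backward so the output has no net phase delay -- essential when
#' filtered signals feed the cross-correlation synchronizer, where a phase
#' lag would bias the estimated clock offset. Single-pass filtering is
#' retained for applications where causal behaviour matters; its -3 dB point
#' sits at `cutoff_hz` per the analytic Butterworth magnitude
#' `|H(f)| = (1 + (f/fc)^(2 * order))^(-1/2)`.
#'
#' @param signal A [sampled_signal()] with at least `3 * order` frames.
#' @param cutoff_hz Cutoff frequency in Hz, strictly below Nyquist.
#' @param order Filter order (default 4).
#' @param zero_phase Forward-backward filtering (default `TRUE`).
#'
#' @return A filtered [sampled_signal()] with identical shape, rate and labels.
#' @export
lowpass_butterworth <- function(signal, cutoff_hz, order = 4L, zero_phase = TRUE) {
  stopifnot(inherits(signal, "sampled_signal"))
  nyquist <- signal$rate_hz / 2
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyquist) {
    stop("cutoff_hz must lie in (0, ", nyquist, ") Hz (Nyquist)", call. = FALSE)
  }
  if (n_frames(signal) < 3L * order) {
    stop("signal too short to filter: need at least ", 3L * order, " frames",
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  out <- signal$values
  for (j in seq_len(ncol(out))) {
    x <- signal$values[, j]
    # filtfilt/filter return constant inputs unchanged only up to FIR edge
    # handling; constants are an exact fixed point of the recursion, so
    # short-circuit them for clean DC behaviour.
    if (max(x) - min(x) == 0) next
    out[, j] <- if (zero_phase) {
      signal::filtfilt(bf, x)
    } else {
      as.numeric(signal::filter(bf, x))
    }
  }
  sampled_signal(out, signal$labels, signal$rate_hz, signal$t0_s)
}

# Best small rational approximation p/q of a positive ratio.
.rational_ratio <- function(ratio, max_den = 4096L, tol = 1e-9) {
  for (q in seq_len(max_den)) {
    p <- round(ratio * q)
    if (p >= 1 && abs(p / q - ratio) < tol * ratio) {
      return(c(p = as.integer(p), q = as.integer(q)))
    }
  }
  stop("cannot approximate resampling ratio ", ratio,
       " by a rational number with denominator <= ", max_den, call. = FALSE)
}

# Band-limited rational resampling of one numeric vector by p/q
# (upsample by zero-stuffing, FIR low-pass via windowed sinc, compensate the
# filter group delay, then decimate). The input is reflect-padded so the
# filter transient falls on the extension rather than the data.
.resample_vector <- function(x, p, q) {
  if (p == q) return(x)
  n <- length(x)
  half <- 10L * max(p, q)
  ntaps <- 2L * half + 1L
  h <- p * signal::fir1(ntaps - 1L, 1 / max(p, q), type = "low",
                        window = signal::hamming(ntaps))
  pad <- min(n - 1L, ceiling(half / p) + 2L)
  xe <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  ne <- length(xe)
  up <- numeric(ne * p)
  up[seq(1L, by = p, length.out = ne)] <- xe
  y <- stats::convolve(up, rev(h), type = "open")
  y <- y[(half + 1L):(half + ne * p)]
  y <- y[(pad * p + 1L):(pad * p + n * p)]
  m <- ceiling(n * p / q)
  y[seq(1L, by = q, length.out = m)]
}

#' Band-limited resampling to a new uniform rate
#'
#' Converts a signal to `target_rate_hz` using polyphase band-limited
#' interpolation (zero-stuffing plus a windowed-sinc anti-aliasing filter
#' with group-delay compensation). Band-limited interpolation rather than
#' linear interpolation is used deliberately: the optical marker stream is
#' acquired at 100 Hz and must be brought to the 128 Hz working rate -- a
#' non-integer ratio -- without distorting landing transients.
#'
#' @param signal A [sampled_signal()] with at least 2 frames.
#' @param target_rate_hz New sampling rate in Hz (> 0).
#'
#' @return A [sampled_signal()] at the target rate. `t0_s` is preserved and
#'   the duration matches the source within one output sample.
#' @export
resample_uniform <- function(signal, target_rate_hz) {
  stopifnot(inherits(signal, "sampled_signal"))
  if (!is.numeric(target_rate_hz) || length(target_rate_hz) != 1L ||
      !is.finite(target_rate_hz) || target_rate_hz <= 0) {
    stop("target_rate_hz must be a single positive number", call. = FALSE)
  }
  if (n_frames(signal) < 2L) {
    stop("resampling needs at least 2 frames", call. = FALSE)
  }
  if (target_rate_hz == signal$rate_hz) return(signal)
  pq <- .rational_ratio(target_rate_hz / signal$rate_hz)
  out <- apply(signal$values, 2L, .resample_vector, p = pq[["p"]], q = pq[["q"]])
  if (is.null(dim(out))) out <- matrix(out, ncol = ncol(signal$values))
  sampled_signal(out, signal$labels, target_rate_hz, signal$t0_s)
}

#' Remove the gravity offset from an acceleration stream
#'
#' Subtracts a per-channel constant offset, estimated as the channel mean
#' over `baseline` when given (a half-open 0-based frame window `c(start,
#' end)` covering a quiet segment), otherwise over the full record. Used on
#' the master-sensor vertical acceleration before the synchronization filter.
#'
#' @param accel A [sampled_signal()] carrying acceleration channels.
#' @param baseline Optional half-open frame window `c(start, end)` (0-based)
#'   over which the offset is estimated; `NULL` uses the full record.
#'
#' @return A [sampled_signal()] with the offset removed.
#' @export
remove_gravity <- function(accel, baseline = NULL) {
  stopifnot(inherits(accel, "sampled_signal"))
  n <- n_frames(accel)
  if (is.null(baseline)) {
    rows <- seq_len(n)
  } else {
    start <- baseline[[1]]; end <- baseline[[2]]
    if (end <= start) stop("empty baseline window", call. = FALSE)
    if (start < 0 || end > n) stop("baseline window out of range", call. = FALSE)
    rows <- (start + 1L):end
  }
  offsets <- colMeans(accel$values[rows, , drop = FALSE])
  sampled_signal(sweep(accel$values, 2L, offsets), accel$labels,
                 accel$rate_hz, accel$t0_s)
}

#' Crop a signal to a half-open frame window
#'
#' All frame windows in this package are half-open and 0-based: frame `k`
#' spans `[t0_s + k/rate, t0_s + (k+1)/rate)`. Cropping advances `t0_s` by
#' `start / rate_hz` so the crop stays on the trial clock.
#'
#' @param signal A [sampled_signal()].
#' @param start,end Frame window `[start, end)`, `0 <= start < end <= n`.
#'
#' @return The cropped [sampled_signal()] with `end - start` frames.
#' @export
crop_frames <- function(signal, start, end) {
  stopifnot(inherits(signal, "sampled_signal"))
  n <- n_frames(signal)
  if (start < 0 || end > n || start >= end) {
    stop("frame window [", start, ", ", end, ") out of range for ", n,
         " frames", call. = FALSE)
  }
  sampled_signal(signal$values[(start + 1L):end, , drop = FALSE],
                 signal$labels, signal$rate_hz,
                 signal$t0_s + start / signal$rate_hz)
}
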