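#' Contact phase of one drop-jump landing
#'
#' A half-open, 0-based frame window on a named stream marking one
#' first-landing phase. Frames are interpreted on the clock of the stream
#' the phase was detected on (`t0_s`, `rate_hz`).
#'
#' @param subject_id Subject identifier.
#' @param jump_id Sequential jump number within the subject's record.
#' @param start_frame,end_frame Half-open frame window, `start < end`.
#' @param rate_hz Sampling rate of the frame indices.
#' @param t0_s Clock time of frame 0 of the underlying stream.
#' @param side Instrumented side; only `"right"` is supported.
#' @return A `contact_phase` object.
#' @export
contact_phase <- function(subject_id, jump_id, start_frame, end_frame,
                          rate_hz, t0_s = 0, side = "right") {
  if (start_frame >= end_frame) {
    stop("contact phase must have start_frame < end_frame", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, jump_id = as.integer(jump_id),
         start_frame = as.integer(start_frame), end_frame = as.integer(end_frame),
         rate_hz = as.numeric(rate_hz), t0_s = as.numeric(t0_s),
         side = match.arg(side, "right")),
    class = "contact_phase"
  )
}

#' @export
print.contact_phase <- function(x, ...) {
  cat(sprintf("<contact_phase> subject %s jump %d: frames [%d, %d) @ %g Hz (%.3f s)\n",
              x$subject_id, x$jump_id, x$start_frame, x$end_frame, x$rate_hz,
              (x$end_frame - x$start_frame) / x$rate_hz))
  invisible(x)
}

#' Detect first-landing contact phases from the vertical GRF
#'
#' Contact is defined on the *unfiltered* vertical ground reaction force: a
#' phase opens at the first frame where the force strictly exceeds
#' `threshold_n` (10 N) and closes at the first subsequent frame at or below
#' it. Spurious chatter around the threshold is handled by merging contacts
#' separated by less than `min_separation_s` of unloaded time and then
#' discarding contacts shorter than `min_duration_s`.
#'
#' A drop jump produces two contacts per jump: the analysed first landing
#' (touch-down after the box drop through take-off into the maximal jump)
#' and the final landing from that jump. With `landing = "first_of_pair"`
#' (default) consecutive contacts are paired in order and only the first of
#' each pair is returned, numbered `jump_id = 1, 2, ...`; use
#' `landing = "all"` to obtain every contact.
#'
#' @param vgrf Single-channel vertical GRF in newtons (unfiltered).
#' @param threshold_n Contact threshold in newtons (default 10).
#' @param min_duration_s Minimum contact duration kept (default 0.1 s).
#' @param min_separation_s Unloaded gaps shorter than this are merged
#'   (default 0.05 s).
#' @param confirm_factor Boundary confirmation margin: the leading/trailing
#'   frames of a contact are kept only if the force reaches
#'   `confirm_factor * threshold_n` within one frame, which stops threshold
#'   chatter immediately adjacent to a genuine onset from widening the
#'   window (default 2; set 1 to disable).
#' @param subject_id Subject identifier carried into the phases.
#' @param landing `"first_of_pair"` (analysis windows) or `"all"`.
#'
#' @return A list of [contact_phase()] objects (possibly empty).
#' @export
detect_contact_phases <- function(vgrf, threshold_n = 10,
                                  min_duration_s = 0.1,
                                  min_separation_s = 0.05,
                                  confirm_factor = 2,
                                  subject_id = NA_character_,
                                  landing = c("first_of_pair", "all")) {
  stopifnot(inherits(vgrf, "sampled_signal"))
  landing <- match.arg(landing)
  if (ncol(vgrf$values) != 1L) {
    stop("detect_contact_phases expects a single-channel vertical GRF",
         call. = FALSE)
  }
  rate <- vgrf$rate_hz
  above <- vgrf$values[, 1] > threshold_n
  if (!any(above)) return(list())

  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  idx <- which(runs$values)
  windows <- cbind(start = starts[idx] - 1L, end = ends[idx])  # half-open 0-based

  # debounce first: isolated noise blips above the threshold must not
  # survive to be merged into a genuine contact's boundary
  keep <- (windows[, "end"] - windows[, "start"]) / rate >= min_duration_s
  windows <- windows[keep, , drop = FALSE]
  if (nrow(windows) == 0L) return(list())

  # merge contacts separated by less than min_separation_s of unloaded time
  min_gap <- min_separation_s * rate
  if (nrow(windows) > 1L) {
    merged <- windows[1, , drop = FALSE]
    for (i in 2:nrow(windows)) {
      if (windows[i, "start"] - merged[nrow(merged), "end"] < min_gap) {
        merged[nrow(merged), "end"] <- windows[i, "end"]
      } else {
        merged <- rbind(merged, windows[i, , drop = FALSE])
      }
    }
    windows <- merged
  }

  # boundary confirmation: trim edge frames that neither reach the confirm
  # level themselves nor are followed (preceded) by a frame that does
  v <- vgrf$values[, 1]
  confirm <- confirm_factor * threshold_n
  for (i in seq_len(nrow(windows))) {
    s <- windows[i, "start"]; e <- windows[i, "end"]
    while (e - s >= 2L && v[s + 1L] <= confirm && v[s + 2L] <= confirm) {
      s <- s + 1L
    }
    while (e - s >= 2L && v[e] <= confirm && v[e - 1L] <= confirm) {
      e <- e - 1L
    }
    windows[i, "start"] <- s; windows[i, "end"] <- e
  }

  if (landing == "first_of_pair") {
    windows <- windows[seq(1L, nrow(windows), by = 2L), , drop = FALSE]
  }
  lapply(seq_len(nrow(windows)), function(j) {
    contact_phase(subject_id, j, windows[j, "start"], windows[j, "end"],
                  rate, vgrf$t0_s)
  })
}

#' Map a contact phase onto another stream
#'
#' Converts the phase's frame window through absolute trial time onto the
#' target stream's frame axis. The start is rounded down and the end up, so
#' the landing window is never clipped when crossing sampling rates.
#'
#' @param phase A [contact_phase()].
#' @param target A [sampled_signal()] sharing the aligned trial clock.
#'
#' @return A [contact_phase()] expressed in the target stream's frames.
#' @export
map_phase_to_stream <- function(phase, target) {
  stopifnot(inherits(phase, "contact_phase"), inherits(target, "sampled_signal"))
  eps <- 1e-9
  start_s <- phase$t0_s + phase$start_frame / phase$rate_hz
  end_s <- phase$t0_s + phase$end_frame / phase$rate_hz
  sf <- floor((start_s - target$t0_s) * target$rate_hz + eps)
  ef <- ceiling((end_s - target$t0_s) * target$rate_hz - eps)
  if (sf < 0 || ef > n_frames(target)) {
    stop("phase [", sf, ", ", ef, ") falls outside the target record (",
         n_frames(target), " frames)", call. = FALSE)
  }
  contact_phase(phase$subject_id, phase$jump_id, sf, ef,
                target$rate_hz, target$t0_s, phase$side)
}
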