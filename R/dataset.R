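#' Canonical 25-column training-table schema
#'
#' The network's training currency is a matched, time-aligned table with one
#' row per 128 Hz frame of a first-landing phase and 25 canonical columns:
#' a per-jump frame index (resetting to 1 at each jump start), 18 IMU
#' predictor channels (gyroscope x/y/z then accelerometer x/y/z for the
#' sacrum (SA), right thigh (RT) and right shank (RL) sensors), and six
#' kinetic targets -- the knee flexion/extension, adduction/abduction and
#' rotation moments (N·m/kg) followed by the three ground reaction force
#' components (N/kg). Tables additionally carry `subject_id` and `jump_id`
#' bookkeeping columns, which are not predictors.
#'
#' @return Character vector of the 25 canonical column names.
#' @export
vdj_schema <- function() {
  sensors <- c("sa", "rt", "rl")
  imu <- unlist(lapply(sensors, function(s) {
    paste(s, c("gyro_x", "gyro_y", "gyro_z", "acc_x", "acc_y", "acc_z"),
          sep = "_")
  }))
  c("frame_index", imu, vdj_target_columns())
}

#' @rdname vdj_schema
#' @export
vdj_predictor_columns <- function() vdj_schema()[1:19]

#' @rdname vdj_schema
#' @export
vdj_target_columns <- function() {
  c("knee_fe", "knee_aa", "knee_r", "grf_x", "grf_y", "grf_z")
}

#' Knee moment sign conventions
#'
#' Axis-wise movement and positive sense used for the three knee moment
#' targets (for documentation and plot labelling).
#'
#' @return A tibble with columns `axis`, `movement`, `positive`, `negative`,
#'   `label`.
#' @export
moment_conventions <- function() {
  tibble::tibble(
    axis = c("x", "y", "z"),
    movement = c("Flexion/Extension", "Adduction/Abduction", "Rotation"),
    positive = c("Flexion", "Varus", "Internal"),
    negative = c("Extension", "Valgus", "External"),
    label = c("FE", "AA", "R")
  )
}

# Channel labels expected on each 6-channel IMU stream.
.imu_channel_labels <- function() {
  c("gyro_x", "gyro_y", "gyro_z", "acc_x", "acc_y", "acc_z")
}

.empty_dataset <- function() {
  cols <- c("subject_id", "jump_id", vdj_schema())
  out <- lapply(cols, function(x) numeric(0))
  names(out) <- cols
  out$subject_id <- character(0)
  out$jump_id <- integer(0)
  out$frame_index <- integer(0)
  tibble::as_tibble(out)
}

#' Build one jump's block of the training table
#'
#' Cuts the aligned, filtered IMU streams and the kinetic targets to one
#' first-landing phase and assembles the canonical 25-column block. IMU
#' streams are low-pass filtered (4th order Butterworth, `imu_cutoff_hz`)
#' *before* cutting, so filter transients fall outside the landing window.
#' Ground reaction forces arrive in newtons and are divided by the subject's
#' body mass (N -> N/kg) at build time; knee moments are already
#' mass-normalized (N·m/kg) and pass through unchanged.
#'
#' @param imu_streams Named list with elements `sa`, `rt`, `rl`; each a
#'   6-channel [sampled_signal()] at the working rate with channel labels
#'   `gyro_x, gyro_y, gyro_z, acc_x, acc_y, acc_z`, aligned to the trial
#'   clock.
#' @param kinetics 6-channel [sampled_signal()] at the working rate with
#'   labels `knee_fe, knee_aa, knee_r, grf_x, grf_y, grf_z`; moments in
#'   N·m/kg, GRFs in newtons.
#' @param phase A [contact_phase()] for the landing window.
#' @param body_mass_kg Subject body mass in kg (> 0).
#' @param imu_cutoff_hz IMU low-pass cutoff in Hz (default 32).
#' @param prefilter Set `FALSE` if the IMU streams are already filtered.
#'
#' @return A tibble block of `L` rows (`L` = phase length at the working
#'   rate) with `subject_id`, `jump_id` and the 25 canonical columns;
#'   `frame_index` runs 1..L.
#' @export
build_jump_block <- function(imu_streams, kinetics, phase, body_mass_kg,
                             imu_cutoff_hz = 32, prefilter = TRUE) {
  stopifnot(inherits(kinetics, "sampled_signal"), inherits(phase, "contact_phase"))
  if (!all(c("sa", "rt", "rl") %in% names(imu_streams))) {
    stop("imu_streams must be a named list with elements sa, rt, rl",
         call. = FALSE)
  }
  if (!is.numeric(body_mass_kg) || body_mass_kg <= 0) {
    stop("body_mass_kg must be positive", call. = FALSE)
  }
  if (!identical(kinetics$labels, vdj_target_columns())) {
    stop("kinetics channels must be ", paste(vdj_target_columns(), collapse = ", "),
         call. = FALSE)
  }
  rate <- kinetics$rate_hz

  kin_phase <- map_phase_to_stream(phase, kinetics)
  L <- kin_phase$end_frame - kin_phase$start_frame
  kin <- crop_frames(kinetics, kin_phase$start_frame, kin_phase$end_frame)
  start_s <- kin$t0_s

  imu_block <- lapply(c(sa = "sa", rt = "rt", rl = "rl"), function(s) {
    str <- imu_streams[[s]]
    stopifnot(inherits(str, "sampled_signal"))
    if (!identical(str$labels, .imu_channel_labels())) {
      stop("IMU stream '", s, "' must carry channels ",
           paste(.imu_channel_labels(), collapse = ", "), call. = FALSE)
    }
    if (abs(str$rate_hz - rate) > 1e-9) {
      stop("IMU stream '", s, "' rate (", str$rate_hz,
           ") differs from the kinetics working rate (", rate, ")", call. = FALSE)
    }
    if (prefilter) str <- lowpass_butterworth(str, imu_cutoff_hz, order = 4L)
    # all working-rate streams share the 1/rate grid after alignment; place
    # the same absolute window on this stream's own frame axis
    sf <- round((start_s - str$t0_s) * rate)
    if (sf < 0 || sf + L > n_frames(str)) {
      stop("phase maps outside IMU stream '", s, "'", call. = FALSE)
    }
    crop_frames(str, sf, sf + L)$values
  })

  targets <- kin$values
  grf_cols <- c("grf_x", "grf_y", "grf_z")
  targets[, grf_cols] <- targets[, grf_cols] / body_mass_kg

  block <- tibble::as_tibble(cbind(imu_block$sa, imu_block$rt, imu_block$rl,
                                   targets), .name_repair = "minimal")
  names(block) <- vdj_schema()[-1]
  tibble::add_column(block,
                     subject_id = as.character(phase$subject_id),
                     jump_id = as.integer(phase$jump_id),
                     frame_index = seq_len(L),
                     .before = 1L)
}

#' Concatenate per-subject tables into the full dataset
#'
#' Row-binds tables that share the canonical schema, preserving subject and
#' jump grouping and the input order.
#'
#' @param tables List of tibbles as produced by [build_jump_block()].
#' @return A single tibble; an empty list yields an empty table with the
#'   canonical schema.
#' @export
concatenate_subjects <- function(tables) {
  if (length(tables) == 0L) return(.empty_dataset())
  schema <- c("subject_id", "jump_id", vdj_schema())
  for (t in tables) {
    if (!identical(names(t), schema)) {
      stop("table schema mismatch: expected the canonical 25-column layout",
           call. = FALSE)
    }
  }
  dplyr::bind_rows(tables)
}

#' Build one dataset per IMU filter cutoff
#'
#' Re-builds the full training table from the *raw* (unfiltered) IMU streams
#' once per cutoff frequency. Only the 18 IMU predictor columns differ
#' between variants; the kinetic targets are identical since they are never
#' re-filtered.
#'
#' @param jump_inputs List of per-jump input lists, each with elements
#'   `imu_streams`, `kinetics`, `phase`, `body_mass_kg` (see
#'   [build_jump_block()]).
#' @param cutoffs Numeric vector of cutoff frequencies in Hz, each below the
#'   working-rate Nyquist (default `c(12, 24, 32)`).
#'
#' @return A named list (one element per cutoff, e.g. `"32"`) of full
#'   datasets.
#' @export
make_filter_variants <- function(jump_inputs, cutoffs = c(12, 24, 32)) {
  rate <- if (length(jump_inputs)) jump_inputs[[1]]$kinetics$rate_hz else 128
  if (any(cutoffs >= rate / 2)) {
    stop("cutoff at or above Nyquist (", rate / 2, " Hz)", call. = FALSE)
  }
  out <- lapply(cutoffs, function(fc) {
    concatenate_subjects(lapply(jump_inputs, function(ji) {
      build_jump_block(ji$imu_streams, ji$kinetics, ji$phase,
                       ji$body_mass_kg, imu_cutoff_hz = fc)
    }))
  })
  names(out) <- as.character(cutoffs)
  out
}

#' Read and write the training table as CSV
#'
#' Plain CSV with the bookkeeping and canonical columns; numeric values are
#' written with 15 significant digits so round trips are lossless to better
#' than 1e-12 relative tolerance.
#'
#' @param dataset A training-table tibble.
#' @param path File path.
#' @return `write_dataset_csv()` returns `path` invisibly;
#'   `read_dataset_csv()` returns the tibble.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- as.data.frame(dataset)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.15g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(subject_id = "character"))
  df$jump_id <- as.integer(df$jump_id)
  df$frame_index <- as.integer(df$frame_index)
  tibble::as_tibble(df)
}
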