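#' Default pipeline configuration
#'
#' Returns the fully populated configuration list used by [run_pipeline()],
#' mirroring the workflow's published defaults: synchronization filter 10 Hz
#' order 4, contact threshold 10 N, IMU dataset cutoff 32 Hz, NARX delays
#' 1:2 with regularization ratio 0.5, and repeated subject-wise 7/4
#' cross-validation.
#'
#' @return Nested named list of configuration sections.
#' @export
default_config <- function() {
  list(
    paths = list(output_dir = "vdj-output"),
    simulate = list(n_subjects = 11L, jumps_per_subject = 10L,
                    target_noise_sd = 0.05, imu_noise_sd = 0.02,
                    misspecify = FALSE, seed = 1L),
    sync = list(cutoff_hz = 10, min_cycles = 5L, band_hz = c(0.5, 3),
                window_ref = NULL, window_other = NULL),
    segment = list(threshold_n = 10, min_duration_s = 0.1,
                   min_separation_s = 0.05),
    build = list(cutoffs = 32),
    narx = list(input_delays = 1:2, feedback_delays = 1:2,
                hidden_sizes = c(1000L, 1000L), activations = "linear",
                regularization_gamma = 0.5, input_scaling = "whiten",
                epochs = 5000L, seed = 1L),
    evaluate = list(n_folds = 20L, n_train = 7L, base_seed = 1L),
    verbose = TRUE
  )
}

.validate_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (sec in names(config)) {
    if (is.list(defaults[[sec]]) && is.list(config[[sec]])) {
      unknown <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
      if (length(unknown)) {
        stop("unknown configuration key(s) in '", sec, "': ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
    }
  }
  merged <- utils::modifyList(defaults, config)
  checks <- list(
    c("segment", "threshold_n"), c("segment", "min_duration_s"),
    c("sync", "cutoff_hz"), c("simulate", "target_noise_sd"),
    c("narx", "epochs"), c("evaluate", "n_folds")
  )
  for (ck in checks) {
    v <- merged[[ck[1]]][[ck[2]]]
    if (!is.numeric(v) || any(v <= 0)) {
      stop("configuration key '", ck[1], ".", ck[2],
           "' must be positive", call. = FALSE)
    }
  }
  if (any(merged$build$cutoffs >= 64)) {
    stop("configuration key 'build.cutoffs' must be below the 64 Hz Nyquist",
         call. = FALSE)
  }
  if (merged$narx$regularization_gamma < 0 || merged$narx$regularization_gamma > 1) {
    stop("configuration key 'narx.regularization_gamma' must lie in [0, 1]",
         call. = FALSE)
  }
  merged
}

#' Load (and validate) a pipeline configuration file
#'
#' Reads a YAML (or JSON) configuration, fills every omitted key with its
#' documented default, validates values, and rejects unknown keys by name.
#' An empty file yields the full default configuration.
#'
#' @param path Path to a YAML/JSON configuration file.
#' @return Validated configuration list.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  .validate_config(cfg)
}

#' Save a configuration to YAML
#' @param config Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Synchronize and segment one recording session
#'
#' Applies the full preprocessing recipe to one session: estimates the
#' optical/inertial clock offset from the trigger spikes ([sync_streams()]),
#' shifts the IMU streams onto the optical clock, detects the first-landing
#' phases on the summed unfiltered vertical GRF, and assembles the kinetics
#' stream (moments passed through at the working rate, right-plate GRFs
#' resampled to it).
#'
#' @param session A `synthetic_session` (or any list with the same stream
#'   fields).
#' @param config Pipeline configuration (see [default_config()]).
#'
#' @return A list: `sync` (the `sync_result`), `phases`, `jump_inputs` (one
#'   element per landing, ready for [build_jump_block()] or
#'   [make_filter_variants()]).
#' @export
process_session <- function(session, config = default_config()) {
  config <- .validate_config(config)
  sy <- config$sync
  res <- sync_streams(session$marker,
                      signal_channel(session$imu$sa, "acc_z"),
                      sync_cutoff_hz = sy$cutoff_hz,
                      window_ref = sy$window_ref,
                      window_other = sy$window_other,
                      min_cycles = sy$min_cycles, band_hz = sy$band_hz)
  imu <- align_streams(session$imu, res)

  sg <- config$segment
  vgrf_sum <- sampled_signal(
    session$grf_right$values[, "grf_z"] + session$grf_left$values[, "grf_z"],
    "vgrf_total", session$grf_right$rate_hz, session$grf_right$t0_s)
  phases <- detect_contact_phases(vgrf_sum, threshold_n = sg$threshold_n,
                                  min_duration_s = sg$min_duration_s,
                                  min_separation_s = sg$min_separation_s,
                                  subject_id = session$subject_id)

  grf128 <- resample_uniform(session$grf_right, session$moments$rate_hz)
  n <- min(n_frames(grf128), n_frames(session$moments))
  kinetics <- sampled_signal(
    cbind(session$moments$values[seq_len(n), , drop = FALSE],
          grf128$values[seq_len(n), , drop = FALSE]),
    vdj_target_columns(), session$moments$rate_hz, session$moments$t0_s)

  jump_inputs <- lapply(phases, function(ph) {
    list(imu_streams = imu, kinetics = kinetics, phase = ph,
         body_mass_kg = session$mass_kg)
  })
  list(sync = res, phases = phases, jump_inputs = jump_inputs)
}

#' Assemble the full training table from a cohort of sessions
#'
#' Runs [process_session()] on every session and builds one dataset per IMU
#' filter cutoff.
#'
#' @param sessions List of sessions (e.g. from [simulate_cohort()]).
#' @param config Pipeline configuration.
#' @return Named list of datasets, one per cutoff in `config$build$cutoffs`.
#' @export
assemble_datasets <- function(sessions, config = default_config()) {
  config <- .validate_config(config)
  jump_inputs <- list()
  for (s in sessions) {
    pr <- process_session(s, config)
    jump_inputs <- c(jump_inputs, pr$jump_inputs)
  }
  make_filter_variants(jump_inputs, cutoffs = config$build$cutoffs)
}

.log <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))

#' Run the full simulate-sync-segment-build-train-evaluate pipeline
#'
#' Orchestrates the whole workflow on a simulated cohort and writes all
#' artifacts to `config$paths$output_dir`: per-cutoff dataset CSVs and
#' cross-validation reports (JSON + CSV), a trained model artifact and test
#' predictions for the primary cutoff, error-histogram figures, and a run
#' manifest recording seeds and parameters.
#'
#' @param config Pipeline configuration (see [default_config()] /
#'   [load_config()]).
#' @return Invisibly, a list with the datasets, reports, and artifact paths.
#' @export
run_pipeline <- function(config = default_config()) {
  config <- .validate_config(config)
  out_dir <- config$paths$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  v <- config$verbose

  sim <- config$simulate
  spec <- cohort_spec(n_subjects = sim$n_subjects,
                      jumps_per_subject = sim$jumps_per_subject,
                      imu_noise_sd = sim$imu_noise_sd,
                      target_noise_sd = sim$target_noise_sd,
                      misspecify = sim$misspecify, seed = sim$seed)
  .log(v, "simulate: %d subjects x %d jumps (seed %d)",
       spec$n_subjects, spec$jumps_per_subject, spec$seed)
  cohort <- simulate_cohort(spec)

  datasets <- assemble_datasets(cohort$sessions, config)
  nx <- config$narx
  ev <- config$evaluate
  cfg <- narx_config(input_delays = nx$input_delays,
                     feedback_delays = nx$feedback_delays,
                     hidden_sizes = nx$hidden_sizes,
                     activations = nx$activations,
                     regularization_gamma = nx$regularization_gamma,
                     input_scaling = nx$input_scaling,
                     epochs = nx$epochs, seed = nx$seed)

  reports <- list()
  paths <- list()
  for (fc in names(datasets)) {
    ds <- datasets[[fc]]
    .log(v, "dataset %s Hz: %d rows, %d jumps", fc, nrow(ds),
         nrow(unique(ds[c("subject_id", "jump_id")])))
    ds_path <- file.path(out_dir, sprintf("dataset_%shz.csv", fc))
    write_dataset_csv(ds, ds_path)
    rep <- cross_validate(ds, cfg, n_folds = ev$n_folds,
                          n_train = ev$n_train, base_seed = ev$base_seed)
    .log(v, "dataset %s Hz: mean test RMSE %.4f",
         fc, mean(rep$summary$mean))
    rep_path <- file.path(out_dir, sprintf("report_%shz.json", fc))
    .write_report(rep, rep_path)
    utils::write.csv(rep$summary,
                     file.path(out_dir, sprintf("report_%shz.csv", fc)),
                     row.names = FALSE)
    fig_path <- file.path(out_dir, sprintf("histograms_%shz.png", fc))
    ggplot2::ggsave(fig_path, plot_error_histograms(rep),
                    width = 8, height = 4, dpi = 150)
    reports[[fc]] <- rep
    paths[[fc]] <- list(dataset = ds_path, report = rep_path,
                        figure = fig_path)
  }

  # final model on the primary (first) cutoff, first-fold split
  primary <- names(datasets)[1]
  ds <- datasets[[primary]]
  sp <- split_subjects(ds$subject_id, n_train = ev$n_train,
                       seed = ev$base_seed)
  fit <- train_rprop(ds[ds$subject_id %in% sp$train, ], cfg)
  model_path <- file.path(out_dir, "model.json")
  narx_save(fit$model, model_path)
  utils::write.csv(
    data.frame(epoch = seq_along(fit$history), performance = fit$history),
    file.path(out_dir, "training_history.csv"), row.names = FALSE)

  test_tab <- ds[ds$subject_id %in% sp$test, ]
  reg <- prepare_regressors(test_tab, cfg)
  pred <- narx_forward(fit$model, reg$X)
  colnames(pred) <- paste0("pred_", vdj_target_columns())
  utils::write.csv(cbind(reg$groups, as.data.frame(pred)),
                   file.path(out_dir, "predictions.csv"), row.names = FALSE)

  manifest <- list(config = config, cohort = cohort$manifest,
                   sync_offsets = lapply(cohort$sessions, function(s) {
                     s$truth$offset_frames
                   }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(list(datasets = datasets, reports = reports, paths = paths,
                 model = fit$model))
}

.write_report <- function(report, path) {
  payload <- list(
    n_folds = report$n_folds, n_train = report$n_train,
    base_seed = report$base_seed,
    summary = as.data.frame(report$summary),
    folds = as.data.frame(report$folds[, !vapply(report$folds, is.list,
                                                 logical(1))]),
    histograms = report$histograms
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
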