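#' Root mean square error per target
#'
#' `RMSE = sqrt(sum((yhat_i - y_i)^2) / n)`, computed per target column over
#' all pooled rows. Row order is irrelevant.
#'
#' @param predicted,actual Aligned matrices (rows x targets) or vectors.
#' @return Named numeric vector of per-target RMSE values.
#' @export
rmse <- function(predicted, actual) {
  if (is.null(dim(predicted))) predicted <- matrix(predicted, ncol = 1L)
  if (is.null(dim(actual))) actual <- matrix(actual, ncol = 1L)
  if (!all(dim(predicted) == dim(actual))) {
    stop("predicted and actual must have identical dimensions", call. = FALSE)
  }
  if (nrow(predicted) == 0L) stop("empty input: RMSE undefined", call. = FALSE)
  out <- sqrt(colMeans((predicted - actual)^2))
  if (!is.null(colnames(actual))) names(out) <- colnames(actual)
  out
}

#' Prediction-error histogram with train/test split
#'
#' Pools the training and test errors, divides the total error range into
#' `n_bins` uniform bins, and counts train and test samples per bin. The
#' position of zero error is reported so plots can mark the unbiased point.
#' If every error is identical the histogram degenerates to a single bin
#' centred on that value and is flagged.
#'
#' @param train_errors,test_errors Numeric error vectors (`yhat - y`);
#'   either may be empty, not both.
#' @param n_bins Number of bins (default 20).
#' @return A list: `breaks` (length `n_bins + 1`), `mids`, `counts_train`,
#'   `counts_test`, `zero_bin` (bin containing zero error, `NA` if outside
#'   the range), `degenerate`.
#' @export
error_histogram <- function(train_errors, test_errors = numeric(0), n_bins = 20L) {
  pooled <- c(train_errors, test_errors)
  if (length(pooled) == 0L) stop("no errors supplied", call. = FALSE)
  lo <- min(pooled); hi <- max(pooled)
  degenerate <- hi == lo
  if (degenerate) {
    breaks <- c(lo - 0.5, lo + 0.5)
    n_bins <- 1L
  } else {
    breaks <- seq(lo, hi, length.out = n_bins + 1L)
  }
  bin_of <- function(e) {
    if (length(e) == 0L) return(integer(n_bins))
    b <- findInterval(e, breaks, rightmost.closed = TRUE, all.inside = TRUE)
    tabulate(b, nbins = n_bins)
  }
  zero_bin <- if (0 >= breaks[1] && 0 <= breaks[n_bins + 1L]) {
    findInterval(0, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  } else {
    NA_integer_
  }
  list(breaks = breaks, mids = (breaks[-1] + breaks[-(n_bins + 1L)]) / 2,
       counts_train = bin_of(train_errors), counts_test = bin_of(test_errors),
       zero_bin = zero_bin, degenerate = degenerate)
}

#' Subject-level train/test split
#'
#' Randomly assigns `n_train` subjects to the training side and the rest to
#' the test side. The split is at the subject level, so no individual's
#' jumps can appear on both sides, and it is reproducible from `seed`.
#'
#' @param subject_ids Vector of subject identifiers (duplicates allowed;
#'   unique values are split).
#' @param n_train Number of training subjects (default 7).
#' @param seed Integer seed.
#' @return A list with `train` and `test` character vectors.
#' @export
split_subjects <- function(subject_ids, n_train = 7L, seed = 1L) {
  ids <- unique(as.character(subject_ids))
  if (length(ids) < n_train + 1L) {
    stop("need at least ", n_train + 1L, " subjects for a ", n_train,
         "/rest split; got ", length(ids), call. = FALSE)
  }
  train <- .with_seed(seed, function() sample(ids, n_train))
  list(train = sort(train), test = sort(setdiff(ids, train)))
}

#' Repeated subject-wise cross-validation of the NARX pipeline
#'
#' Runs `n_folds` independent repeated random subject splits (fold `i` uses
#' seed `base_seed + i - 1` for both the split and the weight
#' initialization), trains a fresh network on each training side, and
#' evaluates open-loop test predictions. Per-target RMSE values are pooled
#' over all test rows of a fold (the error metric is defined over
#' observations, not per jump) and summarized as mean/max/min across folds.
#' Train and test errors pooled across folds feed two 20-bin histograms, one
#' for the GRF targets and one for the moment targets.
#'
#' @param dataset Full training table.
#' @param config A [narx_config()].
#' @param n_folds Number of repeated splits (default 20).
#' @param n_train Training subjects per split (default 7).
#' @param base_seed Seed of the first fold (default 1).
#'
#' @return An `evaluation_report`: `folds` (tibble with per-fold seeds,
#'   subject lists and per-target train/test RMSE), `summary` (tibble of
#'   per-target mean/max/min across folds), `histograms` (`grf`, `moments`),
#'   `n_folds`, `config`.
#' @export
cross_validate <- function(dataset, config, n_folds = 20L, n_train = 7L,
                           base_seed = 1L) {
  stopifnot(inherits(config, "narx_config"))
  ids <- unique(dataset$subject_id)
  if (length(ids) < n_train + 1L) {
    stop("cross-validation needs at least ", n_train + 1L, " subjects",
         call. = FALSE)
  }
  targ <- vdj_target_columns()
  fold_rows <- list()
  err_train <- list(); err_test <- list()

  for (i in seq_len(n_folds)) {
    seed_i <- base_seed + i - 1L
    sp <- split_subjects(dataset$subject_id, n_train = n_train, seed = seed_i)
    cfg_i <- config
    cfg_i$seed <- seed_i
    train_tab <- dataset[dataset$subject_id %in% sp$train, , drop = FALSE]
    test_tab <- dataset[dataset$subject_id %in% sp$test, , drop = FALSE]

    fit <- train_rprop(train_tab, cfg_i)
    reg_tr <- prepare_regressors(train_tab, cfg_i)
    reg_te <- prepare_regressors(test_tab, cfg_i)
    P_tr <- narx_forward(fit$model, reg_tr$X)
    P_te <- narx_forward(fit$model, reg_te$X)

    r_tr <- rmse(P_tr, reg_tr$Y)
    r_te <- rmse(P_te, reg_te$Y)
    names(r_tr) <- names(r_te) <- targ
    err_train[[i]] <- P_tr - reg_tr$Y
    err_test[[i]] <- P_te - reg_te$Y

    row <- tibble::tibble(fold = i, seed = seed_i,
                          train_subjects = list(sp$train),
                          test_subjects = list(sp$test))
    for (k in targ) {
      row[[paste0("train_", k)]] <- r_tr[[k]]
      row[[paste0("test_", k)]] <- r_te[[k]]
    }
    fold_rows[[i]] <- row
  }

  folds <- dplyr::bind_rows(fold_rows)
  summary <- dplyr::bind_rows(lapply(targ, function(k) {
    v <- folds[[paste0("test_", k)]]
    tibble::tibble(target = k, mean = mean(v), max = max(v), min = min(v))
  }))

  grf_idx <- which(targ %in% c("grf_x", "grf_y", "grf_z"))
  mom_idx <- which(targ %in% c("knee_fe", "knee_aa", "knee_r"))
  pool <- function(lst, cols) unlist(lapply(lst, function(m) m[, cols]))
  histograms <- list(
    grf = error_histogram(pool(err_train, grf_idx), pool(err_test, grf_idx)),
    moments = error_histogram(pool(err_train, mom_idx), pool(err_test, mom_idx))
  )

  structure(
    list(folds = folds, summary = summary, histograms = histograms,
         n_folds = n_folds, n_train = n_train, base_seed = base_seed,
         config = config),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d fold(s), %d train subjects per fold\n",
              x$n_folds, x$n_train))
  cat("test RMSE across folds (mean / max / min):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    unit <- if (grepl("^grf", s$target[i])) "N/kg" else "N·m/kg"
    cat(sprintf("  %-8s %.4f / %.4f / %.4f %s\n", s$target[i],
                s$mean[i], s$max[i], s$min[i], unit))
  }
  invisible(x)
}

#' Plot the train/test error histograms of a report
#'
#' Two-panel figure (GRF errors, moment errors) with train and test counts
#' and a vertical marker at zero error.
#'
#' @param report An `evaluation_report`.
#' @return A ggplot object.
#' @export
plot_error_histograms <- function(report) {
  stopifnot(inherits(report, "evaluation_report"))
  frames <- lapply(c(grf = "grf", moments = "moments"), function(g) {
    h <- report$histograms[[g]]
    tibble::tibble(
      group = if (g == "grf") "GRF error (N/kg)" else "Moment error (N·m/kg)",
      mid = rep(h$mids, 2L),
      width = diff(h$breaks)[1],
      set = rep(c("train", "test"), each = length(h$mids)),
      count = c(h$counts_train, h$counts_test)
    )
  })
  df <- dplyr::bind_rows(frames)
  ggplot2::ggplot(df, ggplot2::aes(x = mid, y = count, fill = set)) +
    ggplot2::geom_col(position = "stack", width = df$width * 0.95) +
    ggplot2::geom_vline(xintercept = 0, colour = "orange", linewidth = 0.8) +
    ggplot2::facet_wrap(~group, scales = "free") +
    ggplot2::labs(x = "prediction error", y = "samples", fill = NULL) +
    ggplot2::theme_minimal()
}
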