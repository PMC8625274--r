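#' NARX network configuration
#'
#' The model estimates the six kinetic targets `y(t)` from tapped delay
#' lines over the 19 predictors `u` and the targets themselves:
#' `y(t) = f(y(t-1), ..., y(t-ny), u(t-1), ..., u(t-nu))`,
#' with `f` a fully connected layered network. Training and evaluation use
#' the series-parallel (open-loop) mode, in which the *measured* past
#' targets populate the feedback delay line, so the network is a pure
#' feedforward map of the prepared regressors; the parallel (closed-loop)
#' rollout is provided for completeness.
#'
#' @param input_delays Positive integer delays on the exogenous inputs
#'   (default `1:2`).
#' @param feedback_delays Positive integer delays on the targets
#'   (default `1:2`).
#' @param hidden_sizes Hidden layer widths (default `c(1000, 1000)`, the
#'   full-scale topology; reduced widths are routinely used for testing).
#' @param activations Per-hidden-layer activation names from `"linear"`,
#'   `"tanh"`, `"logsig"`, `"poslin"`; a single name is recycled. The output
#'   layer is always linear. Default `"linear"`.
#' @param regularization_gamma Performance-ratio weight in `[0, 1]`;
#'   the training objective is `gamma * MSE + (1 - gamma) * MSW` where MSW
#'   is the mean squared weight/bias (default 0.5).
#' @param input_scaling Regressor preprocessing fitted on the training set
#'   and frozen into the model artifact: `"whiten"` (default; centre, then
#'   rotate/scale to unit-covariance via SVD -- the tapped delay lines of
#'   smooth 128 Hz signals are nearly collinear, and decorrelating them is
#'   what makes sign-based training converge within the epoch budget),
#'   `"zscore"` (per-column standardization), or `"none"` (raw sensor
#'   scales).
#' @param epochs Training epochs; training always runs to the last epoch
#'   (default 5000; reduced values are used for testing).
#' @param rprop Resilient-backpropagation constants: `delta0` initial step,
#'   `delta_max` step cap, `eta_plus`/`eta_minus` step scaling on
#'   consistent/flipped gradient signs, `delta_min` step floor.
#' @param seed Integer seed for the weight initialization.
#'
#' @return A `narx_config` list.
#' @export
narx_config <- function(input_delays = 1:2, feedback_delays = 1:2,
                        hidden_sizes = c(1000L, 1000L),
                        activations = "linear",
                        regularization_gamma = 0.5,
                        input_scaling = c("whiten", "zscore", "none"),
                        epochs = 5000L,
                        rprop = list(),
                        seed = 1L) {
  input_scaling <- match.arg(input_scaling)
  input_delays <- sort(unique(as.integer(input_delays)))
  feedback_delays <- sort(unique(as.integer(feedback_delays)))
  if (length(input_delays) == 0L || any(input_delays < 1L)) {
    stop("input_delays must be a non-empty set of positive integers", call. = FALSE)
  }
  if (length(feedback_delays) == 0L || any(feedback_delays < 1L)) {
    stop("feedback_delays must be a non-empty set of positive integers", call. = FALSE)
  }
  if (length(hidden_sizes) == 0L || any(hidden_sizes < 1L)) {
    stop("hidden_sizes must be non-empty positive integers", call. = FALSE)
  }
  if (regularization_gamma < 0 || regularization_gamma > 1) {
    stop("regularization_gamma must lie in [0, 1]", call. = FALSE)
  }
  acts <- rep_len(activations, length(hidden_sizes))
  acts <- vapply(acts, function(a) {
    match.arg(a, c("linear", "tanh", "logsig", "poslin"))
  }, character(1), USE.NAMES = FALSE)
  rp <- utils::modifyList(
    list(delta0 = 0.07, delta_max = 50, eta_plus = 1.2, eta_minus = 0.5,
         delta_min = 1e-12),
    rprop
  )
  structure(
    list(input_delays = input_delays, feedback_delays = feedback_delays,
         hidden_sizes = as.integer(hidden_sizes), activations = acts,
         regularization_gamma = regularization_gamma,
         input_scaling = input_scaling,
         epochs = as.integer(epochs), rprop = rp, seed = as.integer(seed)),
    class = "narx_config"
  )
}

.activation <- function(name) {
  switch(name,
         linear = identity,
         tanh = tanh,
         logsig = function(x) 1 / (1 + exp(-x)),
         poslin = function(x) pmax(x, 0))
}

# derivative expressed through the activation output a
.activation_deriv <- function(name, a) {
  switch(name,
         linear = 1,
         tanh = 1 - a^2,
         logsig = a * (1 - a),
         poslin = (a > 0) * 1)
}

# Run fn with a private RNG stream so model seeding never disturbs the
# caller's random state.
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Initialize a NARX model
#'
#' Builds the layered weight matrices and bias vectors. The first layer's
#' input width is `|input_delays| * n_predictors + |feedback_delays| *
#' n_targets`. Weights are drawn uniformly in `±1/sqrt(fan-in)` from a
#' private RNG stream seeded by `config$seed`, so initialization is
#' reproducible and does not perturb the caller's RNG.
#'
#' @param config A [narx_config()].
#' @param n_predictors Number of exogenous inputs (default 19).
#' @param n_targets Number of outputs (default 6).
#' @return A `narx_model` list with elements `config`, `W`, `b`, `layers`.
#' @export
narx_init <- function(config, n_predictors = 19L, n_targets = 6L) {
  stopifnot(inherits(config, "narx_config"))
  in_width <- length(config$input_delays) * n_predictors +
    length(config$feedback_delays) * n_targets
  layers <- c(in_width, config$hidden_sizes, n_targets)
  nl <- length(layers) - 1L
  model <- .with_seed(config$seed, function() {
    W <- vector("list", nl); b <- vector("list", nl)
    for (l in seq_len(nl)) {
      s <- 1 / sqrt(layers[l])
      W[[l]] <- matrix(stats::runif(layers[l] * layers[l + 1L], -s, s),
                       layers[l], layers[l + 1L])
      b[[l]] <- stats::runif(layers[l + 1L], -s, s)
    }
    list(W = W, b = b)
  })
  structure(
    list(config = config, W = model$W, b = model$b, layers = layers,
         n_predictors = as.integer(n_predictors),
         n_targets = as.integer(n_targets)),
    class = "narx_model"
  )
}

#' @export
print.narx_model <- function(x, ...) {
  cat("<narx_model>", paste(x$layers, collapse = " -> "),
      sprintf("(delays u: %s | y: %s; activations: %s)\n",
              paste(x$config$input_delays, collapse = ","),
              paste(x$config$feedback_delays, collapse = ","),
              paste(x$config$activations, collapse = ",")))
  invisible(x)
}

#' Prepare tapped-delay regressors from a training table
#'
#' For each jump group of length `L` the series are shifted by as many steps
#' as needed to fill the delay lines, yielding `L - max(delays)` rows. Each
#' regressor row stacks the delayed predictors then the delayed *measured*
#' targets (series-parallel training): with delays `{1, 2}` the row for time
#' `t` is `[u(t-1), u(t-2), y(t-1), y(t-2)]`. Regressor rows never cross a
#' jump boundary, so the delay lines are always filled from within the same
#' landing. Jumps shorter than `max(delays) + 1` frames are skipped with a
#' warning.
#'
#' @param dataset Training table with `subject_id`, `jump_id` and the
#'   canonical 25 columns.
#' @param config A [narx_config()].
#'
#' @return A `regressor_set` list: `X` (rows x regressor width), `Y`
#'   (aligned target rows), `groups` (tibble of `subject_id`, `jump_id` per
#'   row).
#' @export
prepare_regressors <- function(dataset, config) {
  stopifnot(inherits(config, "narx_config"))
  pred_cols <- vdj_predictor_columns()
  targ_cols <- vdj_target_columns()
  max_d <- max(config$input_delays, config$feedback_delays)
  key <- paste(dataset$subject_id, dataset$jump_id, sep = "\r")
  idx <- split(seq_len(nrow(dataset)), factor(key, levels = unique(key)))

  Xs <- list(); Ys <- list(); Gs <- list(); skipped <- 0L
  for (g in idx) {
    L <- length(g)
    if (L <= max_d) {
      skipped <- skipped + 1L
      next
    }
    U <- as.matrix(dataset[g, pred_cols])
    Y <- as.matrix(dataset[g, targ_cols])
    t_rows <- (max_d + 1L):L
    blocks <- c(
      lapply(config$input_delays, function(d) U[t_rows - d, , drop = FALSE]),
      lapply(config$feedback_delays, function(d) Y[t_rows - d, , drop = FALSE])
    )
    Xs[[length(Xs) + 1L]] <- do.call(cbind, blocks)
    Ys[[length(Ys) + 1L]] <- Y[t_rows, , drop = FALSE]
    Gs[[length(Gs) + 1L]] <- tibble::tibble(
      subject_id = dataset$subject_id[g[t_rows]],
      jump_id = dataset$jump_id[g[t_rows]]
    )
  }
  if (skipped > 0L) {
    warning(skipped, " jump(s) shorter than max delay + 1 were skipped",
            call. = FALSE)
  }
  if (length(Xs) == 0L) {
    stop("no jump is long enough to fill the delay lines", call. = FALSE)
  }
  structure(
    list(X = do.call(rbind, Xs), Y = do.call(rbind, Ys),
         groups = dplyr::bind_rows(Gs)),
    class = "regressor_set"
  )
}

# forward pass keeping all layer activations (for backpropagation)
.forward_full <- function(model, X) {
  nl <- length(model$W)
  A <- vector("list", nl + 1L)
  A[[1]] <- X
  for (l in seq_len(nl)) {
    Z <- sweep(A[[l]] %*% model$W[[l]], 2L, model$b[[l]], "+")
    act <- if (l < nl) model$config$activations[l] else "linear"
    A[[l + 1L]] <- .activation(act)(Z)
  }
  A
}

#' Open-loop (series-parallel) forward pass
#'
#' Deterministic layered evaluation of prepared regressor rows. Because the
#' feedback delay line is filled with measured targets, predictions for
#' different rows are independent of one another.
#'
#' @param model A [narx_init()] model (usually trained).
#' @param X Regressor matrix whose width matches the model's first layer.
#' @return Matrix of predicted targets (rows x 6).
#' @export
narx_forward <- function(model, X) {
  stopifnot(inherits(model, "narx_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$layers[1]) {
    stop("regressor width ", ncol(X), " does not match model input width ",
         model$layers[1], call. = FALSE)
  }
  if (!is.null(model$input_transform)) {
    X <- sweep(X, 2L, model$input_transform$center) %*% model$input_transform$M
  }
  A <- .forward_full(model, X)
  A[[length(A)]]
}

#' Closed-loop (parallel) rollout
#'
#' Autoregressive evaluation feeding predictions back into the feedback
#' delay line. `y_seed` supplies the measured targets for the first
#' `max(delays)` time steps; predictions start at step `max(delays) + 1`.
#'
#' @param model A `narx_model`.
#' @param U Predictor series (L x n_predictors).
#' @param y_seed Matrix of initial target values with at least `max(delays)`
#'   rows.
#' @return L x n_targets matrix; the first `max(delays)` rows echo the seed.
#' @export
narx_forward_closed_loop <- function(model, U, y_seed) {
  stopifnot(inherits(model, "narx_model"))
  cfg <- model$config
  max_d <- max(cfg$input_delays, cfg$feedback_delays)
  if (is.null(dim(y_seed))) y_seed <- matrix(y_seed, ncol = model$n_targets)
  if (nrow(y_seed) < max_d) {
    stop("y_seed must supply at least ", max_d, " rows", call. = FALSE)
  }
  L <- nrow(U)
  Yhat <- matrix(0, L, model$n_targets)
  Yhat[seq_len(max_d), ] <- y_seed[seq_len(max_d), , drop = FALSE]
  for (t in (max_d + 1L):L) {
    x <- c(
      unlist(lapply(cfg$input_delays, function(d) U[t - d, ])),
      unlist(lapply(cfg$feedback_delays, function(d) Yhat[t - d, ]))
    )
    Yhat[t, ] <- narx_forward(model, matrix(x, nrow = 1L))
  }
  Yhat
}

#' Regularized performance of a model
#'
#' `perf = gamma * MSE + (1 - gamma) * MSW`, with MSE the mean squared
#' prediction error over all rows and targets and MSW the mean of the
#' squared weights and biases. At the default ratio 0.5 the two common
#' orderings of the convention coincide.
#'
#' @param model A `narx_model` (for the weight term).
#' @param predictions,targets Aligned prediction/target matrices.
#' @param gamma Optional override of `model$config$regularization_gamma`.
#' @return Scalar performance value.
#' @export
narx_performance <- function(model, predictions, targets, gamma = NULL) {
  stopifnot(inherits(model, "narx_model"))
  if (is.null(gamma)) gamma <- model$config$regularization_gamma
  mse <- mean((predictions - targets)^2)
  theta <- c(unlist(model$W), unlist(model$b))
  msw <- mean(theta^2)
  gamma * mse + (1 - gamma) * msw
}

# flatten / unflatten parameters
.pack <- function(model) c(unlist(model$W), unlist(model$b))
.unpack <- function(theta, model) {
  layers <- model$layers
  nl <- length(layers) - 1L
  off <- 0L
  for (l in seq_len(nl)) {
    k <- layers[l] * layers[l + 1L]
    model$W[[l]] <- matrix(theta[off + seq_len(k)], layers[l], layers[l + 1L])
    off <- off + k
  }
  for (l in seq_len(nl)) {
    k <- layers[l + 1L]
    model$b[[l]] <- theta[off + seq_len(k)]
    off <- off + k
  }
  model
}

# gradient of the regularized performance; returns list(grad, mse, perf)
.perf_gradient <- function(model, X, Y) {
  cfg <- model$config
  gamma <- cfg$regularization_gamma
  nl <- length(model$W)
  A <- .forward_full(model, X)
  P <- A[[nl + 1L]]
  n_el <- length(Y)
  mse <- mean((P - Y)^2)
  delta <- 2 * (P - Y) / n_el          # output layer is linear
  gW <- vector("list", nl); gb <- vector("list", nl)
  for (l in nl:1) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(model$W[[l]])
      delta <- delta * .activation_deriv(cfg$activations[l - 1L], A[[l]])
    }
  }
  theta <- .pack(model)
  grad <- gamma * c(unlist(gW), unlist(gb)) +
    (1 - gamma) * 2 * theta / length(theta)
  list(grad = grad, mse = mse,
       perf = gamma * mse + (1 - gamma) * mean(theta^2))
}

#' Train a NARX model with resilient backpropagation
#'
#' Full-batch training on the regularized mean-squared-error performance.
#' Gradients enter only through their signs: each parameter carries its own
#' step size, grown by `eta_plus` while the gradient sign is stable and
#' shrunk by `eta_minus` when it flips (iRprop- update; the gradient memory
#' is cleared on a flip). Training always runs for exactly `config$epochs`
#' epochs -- there is no early stopping -- and the weight trajectory is fully
#' reproducible from `config$seed`.
#'
#' @param dataset Training table (with `subject_id`, `jump_id` and the
#'   canonical columns) or a prepared `regressor_set`.
#' @param config A [narx_config()].
#' @param n_predictors,n_targets Widths used when `dataset` is already a
#'   `regressor_set` built outside [prepare_regressors()].
#'
#' @return A list with `model` (trained `narx_model`) and `history`
#'   (numeric vector, the regularized performance at the start of each
#'   epoch; length `config$epochs`). The fitted input transform (see
#'   `input_scaling` in [narx_config()]) is stored in the model and
#'   re-applied automatically by [narx_forward()].
#' @export
train_rprop <- function(dataset, config, n_predictors = 19L, n_targets = 6L) {
  stopifnot(inherits(config, "narx_config"))
  if (inherits(dataset, "regressor_set")) {
    reg <- dataset
    n_targets <- ncol(reg$Y)
    exp_width <- ncol(reg$X)
    n_pred <- (exp_width - length(config$feedback_delays) * n_targets) /
      length(config$input_delays)
    n_predictors <- as.integer(round(n_pred))
  } else {
    if (nrow(dataset) == 0L) stop("empty training set", call. = FALSE)
    reg <- prepare_regressors(dataset, config)
    n_predictors <- length(vdj_predictor_columns())
    n_targets <- length(vdj_target_columns())
  }
  if (nrow(reg$X) == 0L) stop("empty training set", call. = FALSE)

  transform <- NULL
  if (config$input_scaling != "none") {
    ctr <- colMeans(reg$X)
    Xc <- sweep(reg$X, 2L, ctr)
    if (config$input_scaling == "zscore") {
      scl <- apply(reg$X, 2L, stats::sd)
      scl[scl == 0] <- 1
      M <- diag(1 / scl, ncol(Xc))
    } else {
      sv <- svd(Xc, nu = 0)
      # floor the spectrum: exactly collinear directions (e.g. delayed
      # frame-index columns differing by a constant) map to ~zero instead
      # of being amplified
      d <- pmax(sv$d, 1e-6 * sv$d[1])
      M <- sv$v %*% diag(sqrt(nrow(Xc) - 1) / d)
    }
    transform <- list(center = ctr, M = M)
    reg$X <- Xc %*% M
  }

  model <- narx_init(config, n_predictors, n_targets)
  theta <- .pack(model)
  np <- length(theta)
  rp <- config$rprop
  delta <- rep(rp$delta0, np)
  g_prev <- numeric(np)
  history <- numeric(config$epochs)

  for (e in seq_len(config$epochs)) {
    model <- .unpack(theta, model)
    g <- .perf_gradient(model, reg$X, reg$Y)
    history[e] <- g$perf
    if (!is.finite(g$perf)) {
      stop("training diverged (non-finite performance) at epoch ", e,
           call. = FALSE)
    }
    gv <- g$grad
    s <- gv * g_prev
    up <- s > 0; down <- s < 0
    delta[up] <- pmin(delta[up] * rp$eta_plus, rp$delta_max)
    delta[down] <- pmax(delta[down] * rp$eta_minus, rp$delta_min)
    gv[down] <- 0
    theta <- theta - sign(gv) * delta
    g_prev <- gv
  }
  model <- .unpack(theta, model)
  model$input_transform <- transform
  list(model = model, history = history)
}

#' Save / load a NARX model artifact
#'
#' The artifact is a single JSON file holding the configuration, layer
#' sizes, and all weights and biases written with 17 significant digits, so
#' a reloaded model reproduces predictions bit-identically.
#'
#' @param model A `narx_model`.
#' @param path File path (`.json`).
#' @return `narx_save()` returns `path` invisibly; `narx_load()` returns the
#'   model.
#' @export
narx_save <- function(model, path) {
  stopifnot(inherits(model, "narx_model"))
  payload <- list(
    format = "vdjkinetics-narx-1",
    config = unclass(model$config),
    layers = model$layers,
    n_predictors = model$n_predictors,
    n_targets = model$n_targets,
    W = lapply(model$W, function(w) list(dim = dim(w), data = as.numeric(w))),
    b = lapply(model$b, function(v) list(data = as.numeric(v))),
    input_transform = if (!is.null(model$input_transform)) {
      list(center = model$input_transform$center,
           M = list(dim = dim(model$input_transform$M),
                    data = as.numeric(model$input_transform$M)))
    }
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname narx_save
#' @export
narx_load <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!identical(p$format, "vdjkinetics-narx-1")) {
    stop("not a NARX model artifact: ", path, call. = FALSE)
  }
  cfg <- narx_config(
    input_delays = p$config$input_delays,
    feedback_delays = p$config$feedback_delays,
    hidden_sizes = p$config$hidden_sizes,
    activations = p$config$activations,
    regularization_gamma = p$config$regularization_gamma,
    input_scaling = p$config$input_scaling,
    epochs = p$config$epochs,
    rprop = as.list(p$config$rprop),
    seed = p$config$seed
  )
  model <- narx_init(cfg, p$n_predictors, p$n_targets)
  model$W <- lapply(p$W, function(w) matrix(w$data, w$dim[1], w$dim[2]))
  model$b <- lapply(p$b, function(v) as.numeric(v$data))
  model$layers <- as.integer(p$layers)
  if (!is.null(p$input_transform)) {
    model$input_transform <- list(
      center = as.numeric(p$input_transform$center),
      M = matrix(p$input_transform$M$data, p$input_transform$M$dim[1],
                 p$input_transform$M$dim[2]))
  }
  model
}
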