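test_that("regressor preparation has the documented geometry", {
  ds <- arx_dataset(n_subjects = 1, jumps = 1, L = 10)
  cfg <- tiny_config()
  reg <- prepare_regressors(ds, cfg)
  expect_equal(nrow(reg$X), 8L)                  # L - max delay
  expect_equal(ncol(reg$X), 19 * 2 + 6 * 2)      # 50

  ds2 <- make_dataset(list(B = list(
    list(U = matrix(rnorm(10 * 18), 10, 18), Y = matrix(rnorm(60), 10, 6)),
    list(U = matrix(rnorm(12 * 18), 12, 18), Y = matrix(rnorm(72), 12, 6))
  )))
  reg2 <- prepare_regressors(ds2, cfg)
  expect_equal(nrow(reg2$X), 8L + 10L)
  # no regressor row mixes jumps
  expect_equal(unname(table(reg2$groups$jump_id)), c(8L, 10L),
               ignore_attr = TRUE)
})

test_that("regressor rows stack delayed inputs then delayed measured targets", {
  ds <- arx_dataset(n_subjects = 1, jumps = 1, L = 3)
  cfg <- tiny_config(input_delays = 1, feedback_delays = 1)
  reg <- prepare_regressors(ds, cfg)
  expect_equal(nrow(reg$X), 2L)
  pred <- as.matrix(ds[, vdj_predictor_columns()])
  targ <- as.matrix(ds[, vdj_target_columns()])
  expect_equal(reg$X[1, ], unname(c(pred[1, ], targ[1, ])),
               ignore_attr = TRUE)
  expect_equal(reg$X[2, ], unname(c(pred[2, ], targ[2, ])),
               ignore_attr = TRUE)
  expect_equal(reg$Y, targ[2:3, ], ignore_attr = TRUE)
})

test_that("jumps shorter than the delay depth are skipped with a warning", {
  short <- make_dataset(list(C = list(
    list(U = matrix(rnorm(2 * 18), 2, 18), Y = matrix(rnorm(12), 2, 6)),
    list(U = matrix(rnorm(9 * 18), 9, 18), Y = matrix(rnorm(54), 9, 6))
  )))
  expect_warning(reg <- prepare_regressors(short, tiny_config()), "skipped")
  expect_equal(nrow(reg$X), 7L)
})

test_that("the open-loop forward pass equals the recurrence oracle exactly", {
  sys <- arx_system()
  ds <- arx_dataset(n_subjects = 1, jumps = 2, L = 25, sys = sys)
  # pass-through hidden layer, known ARX coefficients on the output layer
  cfg <- tiny_config(hidden_sizes = 50L, activations = "linear",
                     input_scaling = "none")
  model <- narx_init(cfg, 19L, 6L)
  model$W[[1]] <- diag(50)
  model$b[[1]] <- rep(0, 50)
  # regressor layout: [u(t-1) (19), u(t-2) (19), y(t-1) (6), y(t-2) (6)]
  W2 <- matrix(0, 50, 6)
  W2[2:19, ] <- t(sys$B1)          # rows 2..19: IMU channels at t-1
  W2[21:38, ] <- t(sys$B2)
  W2[39:44, ] <- t(sys$A1)
  W2[45:50, ] <- t(sys$A2)
  model$W[[2]] <- W2
  model$b[[2]] <- sys$c0
  reg <- prepare_regressors(ds, cfg)
  pred <- narx_forward(model, reg$X)
  expect_equal(pred, reg$Y, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("forward pass is row-independent and validates widths", {
  cfg <- tiny_config(hidden_sizes = c(5L, 4L))
  model <- narx_init(cfg, 19L, 6L)
  X <- matrix(rnorm(10 * 50), 10, 50)
  batch <- narx_forward(model, X)
  rowwise <- t(sapply(1:10, function(i) narx_forward(model, X[i, , drop = FALSE])))
  expect_equal(batch, rowwise, tolerance = 1e-12, ignore_attr = TRUE)
  perm <- sample(10)
  expect_equal(narx_forward(model, X[perm, ]), batch[perm, ])
  expect_error(narx_forward(model, X[, 1:10]), "width")

  zero <- model
  zero$W <- lapply(zero$W, function(w) w * 0)
  zero$b <- lapply(zero$b, function(b) b * 0)
  expect_equal(narx_forward(zero, X), matrix(0, 10, 6), ignore_attr = TRUE)
})

test_that("nonlinear activations are applied as documented", {
  cfg <- tiny_config(hidden_sizes = 3L, activations = "tanh",
                     input_scaling = "none")
  model <- narx_init(cfg, 19L, 6L)
  X <- matrix(rnorm(4 * 50), 4, 50)
  h <- tanh(sweep(X %*% model$W[[1]], 2, model$b[[1]], "+"))
  manual <- sweep(h %*% model$W[[2]], 2, model$b[[2]], "+")
  expect_equal(narx_forward(model, X), manual, tolerance = 1e-12)
})

test_that("closed-loop rollout decays for a stable system and matches open loop when exact", {
  # stable scalar-ish linear model via direct construction
  cfg <- tiny_config(hidden_sizes = 50L, activations = "linear",
                     input_scaling = "none")
  sys <- arx_system()
  model <- narx_init(cfg, 19L, 6L)
  model$W[[1]] <- diag(50); model$b[[1]] <- rep(0, 50)
  W2 <- matrix(0, 50, 6)
  W2[2:19, ] <- t(sys$B1); W2[21:38, ] <- t(sys$B2)
  W2[39:44, ] <- t(sys$A1); W2[45:50, ] <- t(sys$A2)
  model$W[[2]] <- W2; model$b[[2]] <- rep(0, 6)

  # u = 0, spectral radius < 1: rollout decays toward zero
  U0 <- matrix(0, 60, 19)
  seed <- matrix(rnorm(12), 2, 6)
  roll <- narx_forward_closed_loop(model, U0, seed)
  expect_lt(max(abs(roll[55:60, ])), 1e-3 * max(abs(seed)))

  # noise-free system: closed loop reproduces the true series
  ds <- arx_dataset(n_subjects = 1, jumps = 1, L = 30, sys = sys, noise_sd = 0)
  U <- as.matrix(ds[, vdj_predictor_columns()])
  Y <- as.matrix(ds[, vdj_target_columns()])
  model$b[[2]] <- sys$c0
  roll2 <- narx_forward_closed_loop(model, U, Y[1:2, ])
  expect_equal(roll2[3:30, ], Y[3:30, ], tolerance = 1e-9, ignore_attr = TRUE)

  zero <- model
  zero$W <- lapply(zero$W, function(w) w * 0)
  zero$b <- lapply(zero$b, function(b) b * 0)
  expect_equal(narx_forward_closed_loop(zero, U0, seed)[3:60, ],
               matrix(0, 58, 6), ignore_attr = TRUE)
  expect_error(narx_forward_closed_loop(model, U0, seed[1, , drop = FALSE]),
               "seed")
})

test_that("regularized performance combines MSE and MSW as documented", {
  cfg <- tiny_config(hidden_sizes = 2L)
  model <- narx_init(cfg, 19L, 6L)
  zero <- model
  zero$W <- lapply(zero$W, function(w) w * 0)
  zero$b <- lapply(zero$b, function(b) b * 0)
  P <- matrix(rnorm(60), 10, 6)
  expect_equal(narx_performance(zero, P, P), 0)
  Y <- P + 1
  expect_equal(narx_performance(model, P, Y, gamma = 1), 1)
  # gamma 0.5 with known MSE and MSW
  theta <- c(unlist(model$W), unlist(model$b))
  expect_equal(narx_performance(model, P, Y, gamma = 0.5),
               0.5 * 1 + 0.5 * mean(theta^2))
})

test_that("the analytic gradient matches finite differences", {
  cfg <- tiny_config(hidden_sizes = c(4L, 3L), activations = c("tanh", "logsig"),
                     regularization_gamma = 0.7)
  model <- narx_init(cfg, 3L, 2L)     # input width 3*2 + 2*2 = 10
  set.seed(1)
  X <- matrix(rnorm(15 * 10), 15, 10)
  Y <- matrix(rnorm(30), 15, 2)
  g <- vdjkinetics:::.perf_gradient(model, X, Y)
  theta <- vdjkinetics:::.pack(model)
  eps <- 1e-6
  idx <- sample(length(theta), 25)
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    mp <- vdjkinetics:::.unpack(tp, model)
    mm <- vdjkinetics:::.unpack(tm, model)
    pp <- narx_performance(mp, narx_forward(mp, X), Y)
    pm <- narx_performance(mm, narx_forward(mm, X), Y)
    (pp - pm) / (2 * eps)
  }, numeric(1))
  expect_equal(g$grad[idx], num, tolerance = 1e-5)
})

test_that("Rprop training on a linear system approaches the least-squares optimum", {
  ds <- arx_dataset(n_subjects = 3, jumps = 3, L = 40, noise_sd = 0.05)
  cfg <- tiny_config(hidden_sizes = 16L, activations = "linear",
                     regularization_gamma = 1, epochs = 500L, seed = 3L)
  fit <- train_rprop(ds, cfg)
  reg <- prepare_regressors(ds, cfg)
  mse <- mean((narx_forward(fit$model, reg$X) - reg$Y)^2)

  ols <- lm.fit(cbind(1, reg$X), reg$Y)
  coefs <- ols$coefficients
  coefs[is.na(coefs)] <- 0
  ols_mse <- mean((cbind(1, reg$X) %*% coefs - reg$Y)^2)
  expect_lte(mse, 1.05 * ols_mse)
})

test_that("training is deterministic and its history is finite and improving", {
  ds <- arx_dataset(n_subjects = 2, jumps = 2, L = 25, noise_sd = 0.05)
  cfg <- tiny_config(hidden_sizes = 8L, epochs = 60L, seed = 11L,
                     regularization_gamma = 0.5)
  f1 <- train_rprop(ds, cfg)
  f2 <- train_rprop(ds, cfg)
  expect_identical(f1$model$W, f2$model$W)
  expect_identical(f1$model$b, f2$model$b)
  expect_identical(f1$history, f2$history)
  expect_length(f1$history, 60L)

  for (seed in 1:10) {
    cfg_s <- tiny_config(hidden_sizes = 8L, epochs = 60L, seed = seed,
                         regularization_gamma = 0.5)
    fit <- train_rprop(ds, cfg_s)
    expect_true(all(is.finite(fit$history)))
    expect_lte(fit$history[60], fit$history[1])
  }
})

test_that("model artifacts reload to bit-identical predictions", {
  ds <- arx_dataset(n_subjects = 2, jumps = 2, L = 20, noise_sd = 0.05)
  cfg <- tiny_config(hidden_sizes = c(7L, 5L), epochs = 40L,
                     regularization_gamma = 0.5, input_scaling = "whiten")
  fit <- train_rprop(ds, cfg)
  reg <- prepare_regressors(ds, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  narx_save(fit$model, path)
  back <- narx_load(path)
  expect_identical(narx_forward(back, reg$X), narx_forward(fit$model, reg$X))
  expect_identical(back$config$input_delays, cfg$input_delays)
})

test_that("configuration and training inputs are validated", {
  expect_error(narx_config(input_delays = integer(0)), "input_delays")
  expect_error(narx_config(regularization_gamma = 1.5), "gamma")
  expect_error(narx_config(hidden_sizes = integer(0)), "hidden_sizes")
  expect_error(narx_config(activations = "relu6"), "arg")
  ds <- arx_dataset(n_subjects = 1, jumps = 1, L = 10)
  expect_error(train_rprop(ds[0, ], tiny_config()), "empty")
})
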