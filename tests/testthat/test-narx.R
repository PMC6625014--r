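# NARX architecture: tapped-delay regressors, forward pass, channel
# scaling, SCG training, prediction modes, partitioning, persistence.

test_that("regressor assembly matches the hand construction", {
  cfg <- narx_config(input_channels = 1, output_channels = 1,
                     input_taps = 0, output_taps = 1, hidden = 2)
  u <- matrix(c(10, 20, 30)); y <- matrix(c(1, 2, 3))
  reg <- assemble_regressors(u, y, cfg)
  expect_equal(dim(reg$X), c(2, 2))
  expect_equal(reg$X[1, ], c(20, 1))   # u(t), y(t-1) at the first usable frame
  expect_equal(reg$X[2, ], c(30, 2))
  expect_equal(as.vector(reg$Y), c(2, 3))

  # default configuration: 9 input taps x 30 + 8 output taps x 15 = 390
  expect_equal(regressor_dim(narx_config()), 390)

  const <- assemble_regressors(matrix(1, 10, 1), matrix(2, 10, 1), cfg)
  expect_true(all(apply(const$X, 2, function(col) all(col == col[1]))))

  expect_error(assemble_regressors(matrix(1, 1, 1), matrix(1, 1, 1), cfg),
               "shorter")
  expect_error(narx_config(output_taps = 0:3), "exclude lag 0")
})

test_that("forward pass matches a hand-computed one-hidden-unit network", {
  cfg <- narx_config(input_channels = 1, output_channels = 1, hidden = 1,
                     input_taps = 0, output_taps = 1)
  m <- narx_init(cfg)
  m$W1 <- matrix(c(0.5, -0.3), 1, 2); m$b1 <- 0.1
  m$W2 <- matrix(2, 1, 1); m$b2 <- -1
  m$x_scaler <- list(center = 0, half = 1)    # input channel: identity
  m$y_scaler <- list(center = 3, half = 2)    # output channel: y = 2 ys + 3
  x <- c(0.4, -0.2)                           # regressor [u(t), y(t-1)]
  ys_tap <- (-0.2 - 3) / 2                    # y(t-1) scaled into [-1, 1] space
  hand <- (2 / (1 + exp(-(0.5 * 0.4 - 0.3 * ys_tap + 0.1))) - 1) * 2 + 3
  expect_equal(as.vector(narx_forward(m, x)), hand, tolerance = 1e-12)

  # zero weights produce unscale(0) per channel
  m0 <- set_narx_weights(m, rep(0, length(narx_weights(m))))
  expect_equal(as.vector(narx_forward(m0, x)), 3)

  # sigmoid saturation keeps outputs finite for huge inputs
  expect_true(all(is.finite(narx_forward(m, c(1e6, -1e6)))))
  expect_error(narx_forward(m, c(1, 2, 3)), "dimension")
})

test_that("channel scaling round-trips and floors degenerate ranges", {
  set.seed(1)
  X <- cbind(rnorm(50, 3, 10), runif(50, -2, -1), rep(7, 50))
  sc <- fit_scaler(X)
  Xs <- scale_channels(X, sc)
  expect_lte(max(Xs[, 1:2]), 1); expect_gte(min(Xs[, 1:2]), -1)
  expect_equal(unscale_channels(Xs, sc), X, tolerance = 1e-12)
  expect_true(all(is.finite(Xs[, 3])))
})

test_that("analytic gradients match central finite differences", {
  worst <- 0
  for (trial in 1:20) {
    set.seed(trial)
    cfg <- narx_config(input_channels = sample(1:4, 1),
                       output_channels = sample(1:3, 1),
                       hidden = sample(1:6, 1),
                       input_taps = 0:sample(1:3, 1),
                       output_taps = 1:sample(1:3, 1),
                       activation = sample(c("sigmoid", "linear"), 1),
                       seed = trial)
    m <- narx_init(cfg)
    D <- ncol(m$W1)
    Xs <- matrix(rnorm(30 * D), 30, D)
    Ys <- matrix(rnorm(30 * cfg$output_channels), 30, cfg$output_channels)
    w <- narx_weights(m)
    ga <- narx_loss_grad(m, Xs, Ys)$grad
    h <- 1e-6
    gn <- vapply(seq_along(w), function(i) {
      wp <- w; wp[i] <- w[i] + h
      wm <- w; wm[i] <- w[i] - h
      (narx_loss_grad(set_narx_weights(m, wp), Xs, Ys)$loss -
         narx_loss_grad(set_narx_weights(m, wm), Xs, Ys)$loss) / (2 * h)
    }, 0)
    worst <- max(worst, max(abs(ga - gn) / pmax(abs(gn), 1e-4)))
  }
  expect_lt(worst, 1e-6)
})

test_that("SCG drives a linear network to the least-squares solution", {
  set.seed(7)
  cfg <- narx_config(input_channels = 3, output_channels = 2, hidden = 4,
                     input_taps = 0, output_taps = 1, activation = "linear",
                     seed = 3)
  u <- matrix(rnorm(400 * 3), 400, 3)
  A <- matrix(c(1, -2, 0.5, 0.3, 1, -1), 2, 3)
  y <- u %*% t(A)
  reg <- assemble_regressors(u, y, cfg)
  m <- narx_init(cfg)
  fn <- function(w) narx_loss_grad(set_narx_weights(m, w), reg$X, reg$Y)
  opt <- scg_minimize(fn, narx_weights(m), max_iter = 2000)
  pred <- forward_scaled(set_narx_weights(m, opt$w), reg$X)
  ls <- stats::lm.fit(cbind(1, reg$X), reg$Y)$fitted.values
  expect_lt(max(abs(pred - ls)) / stats::sd(y), 1e-6)
})

test_that("SCG training loss is non-increasing at accepted steps", {
  set.seed(2)
  cfg <- narx_config(input_channels = 2, output_channels = 1, hidden = 5,
                     input_taps = 0:1, output_taps = 1, seed = 9)
  u <- matrix(rnorm(300 * 2), 300, 2)
  y <- matrix(sin(u[, 1]) + 0.3 * u[, 2], 300, 1)
  reg <- assemble_regressors(u, y, cfg)
  m <- narx_init(cfg)
  fn <- function(w) narx_loss_grad(set_narx_weights(m, w), reg$X, reg$Y)
  opt <- scg_minimize(fn, narx_weights(m), max_iter = 200)
  expect_true(all(diff(opt$trace) <= 1e-15))
})

test_that("the network recovers a noise-free linear input-output map", {
  # open-loop RMSE < 1% of the target SD on y(t) = A u(t)
  set.seed(5)
  cfg <- narx_config(input_channels = 3, output_channels = 2, hidden = 10,
                     input_taps = 0:2, output_taps = 1:2, max_epochs = 800,
                     patience = 50, seed = 11)
  A <- matrix(c(0.8, -1.2, 0.4, 0.2, 0.9, -0.7), 2, 3)
  mk <- function(n, s) {
    set.seed(s)
    t <- seq_len(n) * 0.01
    u <- cbind(sin(2 * pi * t) + 0.2 * rnorm(n), cos(3 * t), sin(5 * t + 1))
    list(u = u, y = u %*% t(A))
  }
  trials <- lapply(1:4, function(s) mk(400, s))
  fit <- narx_train(lapply(trials, `[[`, "u"), lapply(trials, `[[`, "y"),
                    c("train", "train", "val", "test"), cfg)
  te <- trials[[4]]
  pred <- predict_open_loop(fit$model, te$u, te$y)
  keep <- stats::complete.cases(pred)
  rmse <- sqrt(mean((pred[keep, ] - te$y[keep, ])^2))
  expect_lt(rmse, 0.01 * stats::sd(te$y))
})

test_that("training and prediction are deterministic given the seed", {
  cfg <- narx_config(input_channels = 2, output_channels = 1, hidden = 4,
                     input_taps = 0:1, output_taps = 1, max_epochs = 30,
                     seed = 21)
  mk <- function(s) {
    set.seed(s)
    u <- matrix(rnorm(200 * 2), 200, 2)
    list(u = u, y = matrix(u[, 1] - 0.5 * u[, 2]))
  }
  trials <- lapply(1:3, mk)
  us <- lapply(trials, `[[`, "u"); ys <- lapply(trials, `[[`, "y")
  part <- c("train", "val", "test")
  f1 <- narx_train(us, ys, part, cfg)
  f2 <- narx_train(us, ys, part, cfg)
  expect_identical(f1$report, f2$report)
  expect_identical(narx_weights(f1$model), narx_weights(f2$model))
})

test_that("closed-loop prediction is causal and tracks a converged toy system", {
  # system with genuine output feedback: y(t) = 0.8 y(t-1) + u(t)
  cfg <- narx_config(input_channels = 1, output_channels = 1, hidden = 8,
                     input_taps = 0:1, output_taps = 1:2, max_epochs = 600,
                     patience = 50, seed = 2)
  mk <- function(s) {
    set.seed(s)
    u <- matrix(rnorm(500), 500, 1)
    y <- matrix(0, 500, 1)
    for (t in 2:500) y[t] <- 0.8 * y[t - 1] + u[t]
    list(u = u, y = y)
  }
  trials <- lapply(1:4, mk)
  fit <- narx_train(lapply(trials, `[[`, "u"), lapply(trials, `[[`, "y"),
                    c("train", "train", "val", "test"), cfg)
  te <- trials[[1]]   # self-consistency on a training trial
  op <- predict_open_loop(fit$model, te$u, te$y)
  cl <- predict_closed_loop(fit$model, te$u, y_init = te$y)
  keep <- stats::complete.cases(op)
  rmse_op <- sqrt(mean((op[keep] - te$y[keep])^2))
  rmse_cl <- sqrt(mean((cl[keep] - te$y[keep])^2))
  expect_lt(rmse_cl, 10 * max(rmse_op, 1e-8))

  # boundary: input of exactly max lag + 1 frames yields one prediction
  short <- predict_closed_loop(fit$model, te$u[1:3, , drop = FALSE],
                               y_init = te$y[1:2, , drop = FALSE])
  expect_equal(nrow(short), 3)
  expect_true(all(is.finite(short)))
  expect_error(predict_closed_loop(fit$model, te$u), "y_init")

  # when output taps carry zero weight, closed loop equals open loop
  m0 <- fit$model
  D_in <- length(cfg$input_taps) * 1
  m0$W1[, (D_in + 1):ncol(m0$W1)] <- 0
  op0 <- predict_open_loop(m0, te$u, te$y)
  cl0 <- predict_closed_loop(m0, te$u, y_init = te$y)
  expect_equal(cl0[keep], op0[keep], tolerance = 1e-12)
})

test_that("trial partitioning realizes the 70/15/15 split by whole trials", {
  p200 <- partition_trials(200, seed = 4)
  expect_equal(unname(table(p200)[c("train", "val", "test")]),
               c(140L, 30L, 30L), ignore_attr = TRUE)
  p3 <- partition_trials(3, seed = 4)
  expect_equal(sort(unname(c(table(p3)))), c(1L, 1L, 1L))
  expect_identical(partition_trials(50, seed = 9), partition_trials(50, seed = 9))
  expect_false(identical(partition_trials(50, seed = 9),
                         partition_trials(50, seed = 10)))
  expect_error(partition_trials(2), "at least 3")
})

test_that("model persistence round-trips through the JSON archive", {
  cfg <- narx_config(input_channels = 2, output_channels = 2, hidden = 3,
                     input_taps = 0:1, output_taps = 1:2, seed = 6)
  m <- narx_init(cfg)
  m$x_scaler <- fit_scaler(matrix(rnorm(40), 20, 2))   # per input channel
  path <- tempfile(fileext = ".json")
  save_narx(m, path)
  m2 <- load_narx(path)
  expect_equal(m2$W1, m$W1, tolerance = 1e-12)
  expect_equal(m2$x_scaler$half, unname(m$x_scaler$half), tolerance = 1e-12)
  x <- rnorm(ncol(m$W1))
  expect_equal(narx_forward(m2, x), narx_forward(m, x), tolerance = 1e-12)
})
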