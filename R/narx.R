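# Nonlinear autoregressive network with exogenous inputs (NARX): tapped-delay
# regressor assembly, a single sigmoid hidden layer with linear outputs,
# Moller's scaled-conjugate-gradient batch training with validation-based
# early stopping, and open-loop (teacher-forced) / closed-loop prediction.

#' NARX network configuration
#'
#' Defaults follow the sparse-IMU-to-momentum mapping: 30 input channels,
#' 15 output channels, 30 sigmoid hidden units, linear outputs, the current
#' and eight previous inputs (taps 0..8) and the eight previous outputs
#' (taps 1..8). Output taps must exclude lag 0 (the current output is the
#' prediction target).
#'
#' @param input_channels,output_channels channel counts.
#' @param hidden number of hidden units (>= 1).
#' @param input_taps,output_taps integer lag sets (frames).
#' @param activation hidden activation, `"sigmoid"` (logistic) or `"linear"`.
#' @param max_epochs maximum SCG iterations.
#' @param patience consecutive validation-MSE increases tolerated before
#'   stopping.
#' @param seed seed for weight initialization.
#' @param scg_sigma,scg_lambda0 SCG finite-difference step and initial
#'   Levenberg-Marquardt scale.
#' @return object of class `narx_config`.
#' @export
narx_config <- function(input_channels = 30, output_channels = 15,
                        hidden = 30, input_taps = 0:8, output_taps = 1:8,
                        activation = c("sigmoid", "linear"),
                        max_epochs = 400, patience = 6, seed = 1L,
                        scg_sigma = 5e-5, scg_lambda0 = 5e-7) {
  activation <- match.arg(activation)
  stopifnot(hidden >= 1, length(input_taps) >= 1, length(output_taps) >= 1)
  if (any(output_taps < 1)) stop("output taps must exclude lag 0")
  if (any(input_taps < 0)) stop("input taps must be >= 0")
  structure(list(input_channels = input_channels,
                 output_channels = output_channels, hidden = hidden,
                 input_taps = sort(unique(as.integer(input_taps))),
                 output_taps = sort(unique(as.integer(output_taps))),
                 activation = activation, max_epochs = max_epochs,
                 patience = patience, seed = as.integer(seed),
                 scg_sigma = scg_sigma, scg_lambda0 = scg_lambda0),
            class = "narx_config")
}

regressor_dim <- function(config) {
  length(config$input_taps) * config$input_channels +
    length(config$output_taps) * config$output_channels
}

#' Assemble tapped-delay regressors and aligned targets
#'
#' For each frame `t` past the maximum lag builds the regressor
#' `[u(t-d), d in input taps] ++ [y(t-d), d in output taps]` with the target
#' `y(t)`; teacher forcing uses the ground-truth outputs (open loop).
#'
#' @param u n x input-channels exogenous input sequence.
#' @param y n x output-channels output sequence.
#' @param config a [narx_config()].
#' @return list with `X` (rows = frames, regressors), `Y` (aligned targets)
#'   and `t_index` (the 1-based frame index of each row).
#' @export
assemble_regressors <- function(u, y, config) {
  u <- as.matrix(u); y <- as.matrix(y)
  if (nrow(u) != nrow(y)) stop("input and output sequences differ in length")
  if (ncol(u) != config$input_channels || ncol(y) != config$output_channels)
    stop("channel counts do not match the configuration")
  max_lag <- max(config$input_taps, config$output_taps)
  n <- nrow(u)
  if (n < max_lag + 1) stop("sequence shorter than max lag + 1")
  idx <- (max_lag + 1):n
  blocks <- c(lapply(config$input_taps, function(d) u[idx - d, , drop = FALSE]),
              lapply(config$output_taps, function(d) y[idx - d, , drop = FALSE]))
  list(X = do.call(cbind, blocks), Y = y[idx, , drop = FALSE], t_index = idx)
}

# ---- channel scaling (per-channel min-max onto [-1, 1]) --------------------

fit_scaler <- function(X) {
  lo <- apply(X, 2, min)
  hi <- apply(X, 2, max)
  center <- (hi + lo) / 2
  half <- pmax((hi - lo) / 2, 1e-8)   # floor degenerate ranges
  list(center = center, half = half)
}

scale_channels <- function(X, scaler)
  sweep(sweep(X, 2, scaler$center), 2, scaler$half, `/`)

unscale_channels <- function(X, scaler)
  sweep(sweep(X, 2, scaler$half, `*`), 2, scaler$center, `+`)

# Expand the per-channel input/output scalers over the tap blocks of the
# regressor: [u(t-d) blocks for input taps] ++ [y(t-d) blocks for output taps].
regressor_scaler <- function(model) {
  cfg <- model$config
  list(center = c(rep(model$x_scaler$center, length(cfg$input_taps)),
                  rep(model$y_scaler$center, length(cfg$output_taps))),
       half = c(rep(model$x_scaler$half, length(cfg$input_taps)),
                rep(model$y_scaler$half, length(cfg$output_taps))))
}

# ---- weights ---------------------------------------------------------------

#' Initialize a NARX model
#'
#' Weights drawn uniformly in `[-1/sqrt(fan-in), 1/sqrt(fan-in)]` from a
#' seeded generator; scalers default to identity until fitted.
#'
#' @param config a [narx_config()].
#' @return object of class `narx_model`.
#' @export
narx_init <- function(config) {
  D <- regressor_dim(config)
  h <- config$hidden; q <- config$output_channels
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  r1 <- 1 / sqrt(D); r2 <- 1 / sqrt(h)
  structure(list(
    W1 = matrix(stats::runif(h * D, -r1, r1), h, D),
    b1 = stats::runif(h, -r1, r1),
    W2 = matrix(stats::runif(q * h, -r2, r2), q, h),
    b2 = rep(0, q),
    x_scaler = list(center = rep(0, D), half = rep(1, D)),
    y_scaler = list(center = rep(0, q), half = rep(1, q)),
    config = config, format_version = 1L), class = "narx_model")
}

#' Pack / unpack model weights as a single vector
#' @param model a `narx_model`.
#' @return numeric vector of all weights and biases.
#' @export
narx_weights <- function(model)
  c(as.vector(model$W1), model$b1, as.vector(model$W2), model$b2)

#' @rdname narx_weights
#' @param w packed weight vector.
#' @return `set_narx_weights`: the model with weights replaced.
#' @export
set_narx_weights <- function(model, w) {
  h <- nrow(model$W1); D <- ncol(model$W1); q <- nrow(model$W2)
  stopifnot(length(w) == h * D + h + q * h + q)
  i <- 0
  model$W1 <- matrix(w[i + seq_len(h * D)], h, D); i <- i + h * D
  model$b1 <- w[i + seq_len(h)]; i <- i + h
  model$W2 <- matrix(w[i + seq_len(q * h)], q, h); i <- i + q * h
  model$b2 <- w[i + seq_len(q)]
  model
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass in scaled space. X: N x D (scaled). Returns N x q (scaled).
forward_scaled <- function(model, X) {
  Z <- X %*% t(model$W1)
  Z <- sweep(Z, 2, model$b1, `+`)
  A <- if (model$config$activation == "sigmoid") sigmoid(Z) else Z
  Yh <- A %*% t(model$W2)
  sweep(Yh, 2, model$b2, `+`)
}

#' Forward pass of the NARX network
#'
#' Evaluates `yhat = W2 sigma(W1 x + b1) + b2` in scaled space, then
#' unscales: inputs are scaled by the model's input scaler and outputs by
#' the inverse of its output scaler.
#'
#' @param model a `narx_model`.
#' @param X regressor matrix (rows) or a single regressor vector, raw units.
#' @return predictions in raw output units (rows x output channels).
#' @export
narx_forward <- function(model, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != ncol(model$W1))
    stop("regressor dimension ", ncol(X), " does not match model (",
         ncol(model$W1), ")")
  Xs <- scale_channels(X, regressor_scaler(model))
  unscale_channels(forward_scaled(model, Xs), model$y_scaler)
}

#' Loss and analytic gradient of the NARX network
#'
#' Mean-squared-error loss `E = mean((yhat - y)^2) / 2` over all samples and
#' channels in scaled space, with the exact backpropagated gradient packed
#' in [narx_weights()] order. Used by the SCG optimizer and by
#' finite-difference gradient checks.
#'
#' @param model a `narx_model`.
#' @param Xs,Ys scaled regressors and targets.
#' @return list with `loss` and `grad`.
#' @export
narx_loss_grad <- function(model, Xs, Ys) {
  N <- nrow(Xs); q <- ncol(Ys)
  Z <- sweep(Xs %*% t(model$W1), 2, model$b1, `+`)
  sig <- model$config$activation == "sigmoid"
  A <- if (sig) sigmoid(Z) else Z
  Yh <- sweep(A %*% t(model$W2), 2, model$b2, `+`)
  Err <- Yh - Ys
  loss <- sum(Err^2) / (2 * N * q)
  dY <- Err / (N * q)
  gW2 <- crossprod(dY, A)          # q x h
  gb2 <- colSums(dY)
  dA <- dY %*% model$W2            # N x h
  dZ <- if (sig) dA * A * (1 - A) else dA
  gW1 <- crossprod(dZ, Xs)         # h x D
  gb1 <- colSums(dZ)
  list(loss = loss,
       grad = c(as.vector(gW1), gb1, as.vector(gW2), gb2))
}
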