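# Moller's scaled conjugate gradient: a second-order batch optimizer using
# Hessian-vector products approximated by finite-differencing the gradient,
# with Levenberg-Marquardt lambda adaptation and periodic restarts.

#' Scaled-conjugate-gradient minimization
#'
#' Minimizes a smooth objective given a combined loss/gradient function.
#' One call of `fn` returns `list(loss, grad)`. The conjugate direction is
#' restarted every `length(w0)` iterations; the Hessian-vector product is
#' approximated as `(grad(w + sigma p) - grad(w)) / sigma`.
#'
#' @param fn function(w) -> list(loss, grad).
#' @param w0 initial parameter vector.
#' @param max_iter maximum iterations.
#' @param sigma0 finite-difference scale (default 5e-5).
#' @param lambda0 initial lambda (default 5e-7).
#' @param grad_tol stop when the direction norm falls below this.
#' @param callback optional function(iter, w, loss) -> TRUE to stop early;
#'   called after every accepted step.
#' @return list with `w`, `loss`, `iterations`, `lambda`, `trace` (accepted
#'   loss per iteration) and `reason`.
#' @export
scg_minimize <- function(fn, w0, max_iter = 250, sigma0 = 5e-5,
                         lambda0 = 5e-7, grad_tol = 1e-10,
                         callback = NULL) {
  w <- w0
  N <- length(w)
  fg <- fn(w)
  if (!is.finite(fg$loss)) stop("non-finite loss at the starting point")
  E <- fg$loss
  r <- -fg$grad
  p <- r
  lambda <- lambda0; lambdabar <- 0
  success <- TRUE
  trace <- numeric(0)
  reason <- "max iterations reached"
  k <- 1
  delta <- 0; pn2 <- sum(p * p)
  for (iter in seq_len(max_iter)) {
    if (success) {
      pn2 <- sum(p * p)
      if (sqrt(pn2) < grad_tol) { reason <- "gradient vanished"; break }
      sigma <- sigma0 / sqrt(pn2)
      gplus <- fn(w + sigma * p)$grad
      s <- (gplus + r) / sigma          # (E'(w+sp) - E'(w)) / s, E'(w) = -r
      delta <- sum(p * s)
    }
    delta_k <- delta + (lambda - lambdabar) * pn2
    if (delta_k <= 0) {                 # make the Hessian estimate SPD
      lambdabar <- 2 * (lambda - delta_k / pn2)
      delta_k <- -delta_k + lambda * pn2
      lambda <- lambdabar
    }
    mu <- sum(p * r)
    alpha <- mu / delta_k
    fg_new <- fn(w + alpha * p)
    if (!is.finite(fg_new$loss))
      stop("non-finite loss during SCG at iteration ", iter)
    Delta <- 2 * delta_k * (E - fg_new$loss) / mu^2
    if (Delta >= 0) {                   # accept the step
      w <- w + alpha * p
      E <- fg_new$loss
      rnew <- -fg_new$grad
      lambdabar <- 0
      success <- TRUE
      if (k %% N == 0) {
        p <- rnew                       # periodic restart
      } else {
        beta <- (sum(rnew * rnew) - sum(rnew * r)) / mu
        p <- rnew + beta * p
      }
      r <- rnew
      if (Delta >= 0.75) lambda <- lambda / 4
      trace <- c(trace, E)
      if (!is.null(callback) && isTRUE(callback(length(trace), w, E))) {
        reason <- "early stopping"
        break
      }
    } else {
      lambdabar <- lambda
      success <- FALSE
    }
    if (Delta < 0.25) lambda <- lambda + delta_k * (1 - Delta) / pn2
    lambda <- min(lambda, 1e20)
    k <- k + 1
  }
  list(w = w, loss = E, iterations = k - 1, lambda = lambda,
       trace = trace, reason = reason)
}

#' Train a NARX model with scaled conjugate gradient
#'
#' Fits per-channel min-max scalers on the training sequences only,
#' assembles teacher-forced (open-loop) tapped-delay regressors per trial,
#' and minimizes the training MSE by SCG. After every accepted step the
#' validation MSE is evaluated; the returned model carries the weights with
#' the best validation MSE, and training stops after `patience` consecutive
#' validation increases or `max_epochs` iterations.
#'
#' @param inputs list of n x input-channel matrices (one per trial).
#' @param outputs list of aligned n x output-channel matrices.
#' @param partition character vector (`"train"`, `"val"`, `"test"`) per trial.
#' @param config a [narx_config()].
#' @return list with `model` (best-validation `narx_model`) and `report`
#'   (class `narx_report`): per-epoch train/val/test MSE, stopping epoch and
#'   reason, seed and final lambda.
#' @export
narx_train <- function(inputs, outputs, partition, config = narx_config()) {
  stopifnot(length(inputs) == length(outputs),
            length(partition) == length(inputs))
  if (!any(partition == "train")) stop("no training trials")
  model <- narx_init(config)
  tr <- which(partition == "train")
  model$x_scaler <- fit_scaler(do.call(rbind, inputs[tr]))
  model$y_scaler <- fit_scaler(do.call(rbind, outputs[tr]))

  sets <- lapply(c(train = "train", val = "val", test = "test"), function(p) {
    ix <- which(partition == p)
    if (!length(ix)) return(NULL)
    regs <- lapply(ix, function(i)
      assemble_regressors(inputs[[i]], outputs[[i]], config))
    list(X = scale_channels(do.call(rbind, lapply(regs, `[[`, "X")),
                            regressor_scaler(model)),
         Y = scale_channels(do.call(rbind, lapply(regs, `[[`, "Y")),
                            model$y_scaler))
  })

  mdl <- model  # reused container for loss/grad evaluation
  fn <- function(w) narx_loss_grad(set_narx_weights(mdl, w),
                                   sets$train$X, sets$train$Y)
  mse_of <- function(w, set) {
    if (is.null(set)) return(NA_real_)
    m <- set_narx_weights(mdl, w)
    mean((forward_scaled(m, set$X) - set$Y)^2)
  }

  hist_train <- numeric(0); hist_val <- numeric(0); hist_test <- numeric(0)
  best_val <- Inf; best_w <- narx_weights(model); best_epoch <- 0
  streak <- 0; prev_val <- Inf
  cb <- function(iter, w, loss) {
    hist_train[iter] <<- 2 * loss       # loss = MSE/2
    v <- mse_of(w, sets$val)
    hist_val[iter] <<- v
    hist_test[iter] <<- mse_of(w, sets$test)
    if (is.na(v)) return(FALSE)
    if (v < best_val) { best_val <<- v; best_w <<- w; best_epoch <<- iter }
    streak <<- if (v > prev_val) streak + 1 else 0
    prev_val <<- v
    streak >= config$patience
  }
  opt <- scg_minimize(fn, narx_weights(model), max_iter = config$max_epochs,
                      sigma0 = config$scg_sigma, lambda0 = config$scg_lambda0,
                      callback = cb)
  final_w <- if (is.finite(best_val)) best_w else opt$w
  model <- set_narx_weights(model, final_w)
  report <- structure(list(train_mse = hist_train, val_mse = hist_val,
                           test_mse = hist_test,
                           stopping_epoch = opt$iterations,
                           best_epoch = if (is.finite(best_val)) best_epoch
                                        else opt$iterations,
                           reason = opt$reason, seed = config$seed,
                           lambda = opt$lambda), class = "narx_report")
  list(model = model, report = report)
}

#' @export
print.narx_report <- function(x, ...) {
  cat("<narx_report>", x$stopping_epoch, "epochs (", x$reason, ")\n")
  if (length(x$train_mse))
    cat("  final train MSE:", signif(utils::tail(x$train_mse, 1), 4),
        " best val MSE:", signif(min(x$val_mse, na.rm = TRUE), 4),
        "at epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Open-loop (teacher-forced) prediction
#'
#' Fills the output delay taps with ground-truth past outputs. The first
#' `max lag` frames cannot be predicted and are returned as `NA`.
#'
#' @param model a trained `narx_model`.
#' @param u n x input-channels sequence.
#' @param y n x output-channels ground-truth sequence (for the delay taps).
#' @return n x output-channels prediction matrix (leading rows `NA`).
#' @export
predict_open_loop <- function(model, u, y) {
  reg <- assemble_regressors(u, y, model$config)
  pred <- matrix(NA_real_, nrow(as.matrix(u)), model$config$output_channels)
  pred[reg$t_index, ] <- narx_forward(model, reg$X)
  colnames(pred) <- colnames(y)
  pred
}

#' Closed-loop (simulation) prediction
#'
#' Fills the output delay taps with the model's own previous predictions,
#' processing strictly causally. The output history for the first `max lag`
#' frames is seeded from ground truth (`init = "history"`, requires `y_init`)
#' or zeros (`init = "zeros"`).
#'
#' @param model a trained `narx_model`.
#' @param u n x input-channels sequence (n >= max lag + 1).
#' @param y_init matrix providing at least `max lag` initial output frames.
#' @param init `"history"` (default) or `"zeros"`.
#' @return n x output-channels prediction matrix; the first `max lag` rows
#'   echo the initialization.
#' @export
predict_closed_loop <- function(model, u, y_init = NULL,
                                init = c("history", "zeros")) {
  init <- match.arg(init)
  cfg <- model$config
  u <- as.matrix(u)
  max_lag <- max(cfg$input_taps, cfg$output_taps)
  n <- nrow(u)
  if (n < max_lag + 1) stop("input shorter than max lag + 1")
  yhat <- matrix(0, n, cfg$output_channels)
  if (init == "history") {
    if (is.null(y_init)) stop("y_init required when init = 'history'")
    y_init <- as.matrix(y_init)
    if (nrow(y_init) < max_lag) stop("y_init must cover the first max-lag frames")
    yhat[seq_len(max_lag), ] <- y_init[seq_len(max_lag), , drop = FALSE]
  }
  us <- scale_channels(u, model$x_scaler)
  D_in <- length(cfg$input_taps) * cfg$input_channels
  ys <- matrix(0, n, cfg$output_channels)
  ys[seq_len(max_lag), ] <- scale_channels(
    yhat[seq_len(max_lag), , drop = FALSE], model$y_scaler)
  for (t in (max_lag + 1):n) {
    xin <- unlist(lapply(cfg$input_taps, function(d) us[t - d, ]))
    xout <- unlist(lapply(cfg$output_taps, function(d) ys[t - d, ]))
    z <- model$W1 %*% c(xin, xout) + model$b1
    a <- if (cfg$activation == "sigmoid") sigmoid(z) else z
    ys[t, ] <- as.vector(model$W2 %*% a + model$b2)
  }
  out <- unscale_channels(ys, model$y_scaler)
  out[seq_len(max_lag), ] <- yhat[seq_len(max_lag), ]
  out
}

#' Randomly partition trials into train / validation / test
#'
#' Partitions whole trials (never frames, which are autocorrelated within a
#' trial) into the three sets. Fractions are realized as closely as counts
#' allow with at least one trial per set; reproducible by seed.
#'
#' @param x a `trial_set` or an integer trial count.
#' @param fractions train/val/test fractions summing to 1 (default
#'   0.70/0.15/0.15).
#' @param seed integer seed.
#' @return for a count: character label vector; for a `trial_set`: the set
#'   with its `partition` slot filled.
#' @export
partition_trials <- function(x, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  n <- if (inherits(x, "trial_set")) length(x$trials) else as.integer(x)
  if (n < 3) stop("need at least 3 trials to partition")
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  n_val <- max(1L, round(fractions[2] * n))
  n_test <- max(1L, round(fractions[3] * n))
  n_train <- n - n_val - n_test
  if (n_train < 1) stop("fractions leave no training trials")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  labels <- character(n)
  labels[ord[seq_len(n_train)]] <- "train"
  labels[ord[n_train + seq_len(n_val)]] <- "val"
  labels[ord[n_train + n_val + seq_len(n_test)]] <- "test"
  if (inherits(x, "trial_set")) {
    x$partition <- labels
    x
  } else labels
}

#' Save / load a NARX model as a single JSON archive
#'
#' The archive holds weights, biases, channel scalers, configuration, seed
#' and a format-version field.
#'
#' @param model a `narx_model`.
#' @param path file path.
#' @return `load_narx`: the restored `narx_model`.
#' @export
save_narx <- function(model, path) {
  obj <- list(format_version = model$format_version,
              W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
              x_scaler = model$x_scaler, y_scaler = model$y_scaler,
              config = unclass(model$config))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_narx
#' @export
load_narx <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  config <- narx_config(cfg$input_channels, cfg$output_channels, cfg$hidden,
                        cfg$input_taps, cfg$output_taps, cfg$activation,
                        cfg$max_epochs, cfg$patience, cfg$seed,
                        cfg$scg_sigma, cfg$scg_lambda0)
  structure(list(W1 = obj$W1, b1 = obj$b1, W2 = obj$W2, b2 = obj$b2,
                 x_scaler = lapply(obj$x_scaler, as.numeric),
                 y_scaler = lapply(obj$y_scaler, as.numeric),
                 config = config,
                 format_version = obj$format_version), class = "narx_model")
}

#' @export
print.narx_model <- function(x, ...) {
  cfg <- x$config
  cat("<narx_model>", cfg$input_channels, "in /", cfg$output_channels,
      "out,", cfg$hidden, cfg$activation, "hidden units,",
      length(cfg$input_taps), "input taps,", length(cfg$output_taps),
      "output taps (regressor dim", ncol(x$W1), ")\n")
  invisible(x)
}
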