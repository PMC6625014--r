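# Accuracy metrics and the end-to-end surrogate experiment: pooled Pearson
# correlation, peak-normalized RMS error per momentum channel, and the
# generate -> train -> perturb -> test pipeline.

#' Pooled Pearson correlation
#'
#' Pearson correlation between predicted and actual values pooled over all
#' frames, channels and (if lists are given) trials, concatenated into two
#' vectors. `NA` rows (e.g. the unpredictable leading lag frames of
#' open-loop prediction) are dropped pairwise.
#'
#' @param predicted,actual matrices, or lists of matrices with matching
#'   shapes.
#' @return scalar correlation coefficient in `[-1, 1]`.
#' @export
pooled_correlation <- function(predicted, actual) {
  if (is.list(predicted)) predicted <- do.call(rbind, predicted)
  if (is.list(actual)) actual <- do.call(rbind, actual)
  if (!all(dim(predicted) == dim(actual)))
    stop("predicted and actual shapes differ")
  p <- as.vector(predicted); a <- as.vector(actual)
  keep <- is.finite(p) & is.finite(a)
  p <- p[keep]; a <- a[keep]
  if (length(p) < 2) stop("need at least 2 paired samples")
  if (stats::sd(p) == 0 || stats::sd(a) == 0)
    stop("correlation undefined: zero-variance input")
  stats::cor(p, a)
}

#' Peak-normalized RMS error per channel
#'
#' For each channel, 100 x RMS(predicted - actual) / max |actual|, the RMS
#' error as a percentage of the peak signal magnitude of that channel in
#' this trial. Channels whose actual signal is identically (near) zero get
#' `NA` with a warning.
#'
#' @param predicted,actual aligned matrices (frames x channels); `NA` rows
#'   in `predicted` are dropped pairwise.
#' @return named numeric vector, one percentage per channel.
#' @export
normalized_rms_error <- function(predicted, actual) {
  if (!all(dim(predicted) == dim(actual)))
    stop("predicted and actual shapes differ")
  keep <- stats::complete.cases(predicted)
  p <- predicted[keep, , drop = FALSE]
  a <- actual[keep, , drop = FALSE]
  peak <- apply(abs(a), 2, max)
  rms <- sqrt(colMeans((p - a)^2))
  out <- 100 * rms / peak
  if (any(peak < 1e-12)) {
    warning("zero peak signal magnitude in channel(s): ",
            paste(colnames(actual)[peak < 1e-12], collapse = ", "))
    out[peak < 1e-12] <- NA_real_
  }
  names(out) <- colnames(actual)
  out
}

#' Evaluate a trained model on a cohort
#'
#' Predicts each trial (open- or closed-loop) and computes the pooled
#' correlation, per-trial per-channel peak-normalized RMS errors with their
#' cohort mean and SD, per-channel pooled correlations, and a per-task
#' pooled correlation breakdown when task labels are supplied.
#'
#' @param model a trained `narx_model`.
#' @param inputs list of (noisy) 30-channel IMU matrices.
#' @param outputs list of gold-standard 15-channel momentum matrices.
#' @param mode `"open"` (teacher-forced) or `"closed"` (simulation).
#' @param labels optional list of per-frame task-label vectors.
#' @return list with `pooled_r`, `rms_mean`, `rms_sd`, `rms_per_trial`,
#'   `channel_r`, `task_r`, `mode`.
#' @export
evaluate_cohort <- function(model, inputs, outputs, mode = c("open", "closed"),
                            labels = NULL) {
  mode <- match.arg(mode)
  preds <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    preds[[i]] <- if (mode == "open")
      predict_open_loop(model, inputs[[i]], outputs[[i]])
    else {
      pr <- predict_closed_loop(model, inputs[[i]], y_init = outputs[[i]])
      max_lag <- max(model$config$input_taps, model$config$output_taps)
      pr[seq_len(max_lag), ] <- NA    # exclude the seeded history from scoring
      pr
    }
  }
  rms <- t(vapply(seq_along(preds), function(i)
    normalized_rms_error(preds[[i]], unclass(outputs[[i]])),
    numeric(ncol(outputs[[1]]))))
  P <- do.call(rbind, preds)
  A <- do.call(rbind, lapply(outputs, unclass))
  channel_r <- vapply(seq_len(ncol(A)), function(j)
    pooled_correlation(P[, j, drop = FALSE], A[, j, drop = FALSE]), 0)
  names(channel_r) <- colnames(A)
  task_r <- NULL
  if (!is.null(labels)) {
    lab <- unlist(labels, use.names = FALSE)
    task_r <- vapply(sort(unique(lab)), function(tk)
      pooled_correlation(P[lab == tk, , drop = FALSE],
                         A[lab == tk, , drop = FALSE]), 0)
  }
  list(pooled_r = pooled_correlation(P, A),
       rms_mean = colMeans(rms), rms_sd = apply(rms, 2, stats::sd),
       rms_per_trial = rms, channel_r = channel_r, task_r = task_r,
       mode = mode, predictions = preds)
}

#' Default experiment configuration
#'
#' Study conditions of the surrogate experiment: a 70-trial able-bodied-style
#' training cohort (five anthropometric profiles, ~10 s trials at 100 Hz over
#' the default circuit), a 20-trial perturbed-gait surrogate test cohort,
#' 70/15/15 trial partition, clean training inputs, and test-time Gaussian
#' sensor noise (0.15 m/s^2, 0.005 rad/s).
#'
#' @param n_trials able-bodied cohort size.
#' @param n_surrogate perturbed-cohort size.
#' @param circuit a [circuit_spec()].
#' @param style a [gait_style()].
#' @param narx a [narx_config()].
#' @param accel_sigma,gyro_sigma test-time sensor-noise SDs.
#' @param fractions train/val/test fractions.
#' @param seed master seed; all stage seeds derive from it.
#' @param cutoff,ma_window marker filter cutoff (Hz) and moving-average
#'   width (frames).
#' @param closed_loop also evaluate closed-loop simulation (slower).
#' @return configuration list for [run_experiment()].
#' @export
experiment_config <- function(n_trials = 70, n_surrogate = 20,
                              circuit = circuit_spec(), style = gait_style(),
                              narx = narx_config(),
                              accel_sigma = 0.15, gyro_sigma = 0.005,
                              fractions = c(0.70, 0.15, 0.15), seed = 1L,
                              cutoff = 6, ma_window = 5,
                              closed_loop = TRUE) {
  as.list(environment())
}

trial_channels <- function(trial, cutoff, ma_window) {
  sm <- smooth_markers(trial$markers, cutoff = cutoff, rate = trial$rate)
  poses <- fit_segment_poses(sm, trial$model)
  trace <- momentum_trace(poses = poses, model = trial$model,
                          rate = trial$rate, ma_window = ma_window)
  list(sm = sm, trace = trace)
}

#' Run the end-to-end surrogate experiment
#'
#' Generates the able-bodied-style cohort; computes gold-standard momentum
#' traces (marker smoothing, rigid pose tracking, Eq.-based momenta in the
#' body frame, height x mass normalization, moving average) and clean
#' virtual-IMU streams; partitions by whole trial; trains the NARX network
#' with SCG on the training partition; then evaluates open-loop (and
#' optionally closed-loop) on the held-out test partition and on a freshly
#' generated perturbed-gait surrogate cohort, both with test-time sensor
#' noise injected. All randomness derives from the master seed.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress.
#' @return object of class `experiment_report`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  seed <- config$seed

  say("generating able-bodied cohort (", config$n_trials, " trials)")
  cohort <- make_cohort(config$n_trials, able_bodied_profiles(),
                        config$circuit, config$style,
                        seed = derive_seed(seed, 1))
  say("computing momenta and clean IMU streams")
  chans <- lapply(cohort$trials, trial_channels,
                  cutoff = config$cutoff, ma_window = config$ma_window)
  traces <- lapply(chans, function(ch) unclass(ch$trace))
  imus_clean <- lapply(chans, function(ch)
    unclass(imu_stream(ch$sm, rate = config$circuit$rate,
                       ma_window = config$ma_window)))

  partition <- partition_trials(length(cohort$trials), config$fractions,
                                seed = derive_seed(seed, 2))
  say("training NARX (", sum(partition == "train"), " training trials)")
  fit <- narx_train(imus_clean, traces, partition, config$narx)

  noisy_imu <- function(ch, k)
    unclass(imu_stream(ch$sm, rate = config$circuit$rate,
                       noise = noise_spec(config$accel_sigma,
                                          config$gyro_sigma,
                                          seed = derive_seed(seed, 1000 + k)),
                       ma_window = config$ma_window))

  test_ix <- which(partition == "test")
  say("evaluating on ", length(test_ix), " held-out test trials (noise on)")
  test_in <- lapply(seq_along(test_ix), function(j)
    noisy_imu(chans[[test_ix[j]]], j))
  test_out <- traces[test_ix]
  test_labels <- lapply(cohort$trials[test_ix], `[[`, "labels")
  ev_able <- evaluate_cohort(fit$model, test_in, test_out, "open",
                             labels = test_labels)
  ev_able_cl <- if (config$closed_loop)
    evaluate_cohort(fit$model, test_in, test_out, "closed") else NULL

  say("generating perturbed-gait surrogate cohort (", config$n_surrogate,
      " trials)")
  pd_style <- pd_surrogate(config$style)
  pd_cohort <- make_cohort(config$n_surrogate, pd_profiles(),
                           config$circuit, pd_style,
                           seed = derive_seed(seed, 3))
  pd_chans <- lapply(pd_cohort$trials, trial_channels,
                     cutoff = config$cutoff, ma_window = config$ma_window)
  pd_in <- lapply(seq_along(pd_chans), function(j)
    noisy_imu(pd_chans[[j]], 5000 + j))
  pd_out <- lapply(pd_chans, function(ch) unclass(ch$trace))
  pd_labels <- lapply(pd_cohort$trials, `[[`, "labels")
  say("evaluating on the surrogate cohort (no retraining, noise on)")
  ev_pd <- evaluate_cohort(fit$model, pd_in, pd_out, "open",
                           labels = pd_labels)
  ev_pd_cl <- if (config$closed_loop)
    evaluate_cohort(fit$model, pd_in, pd_out, "closed") else NULL

  structure(list(model = fit$model, train_report = fit$report,
                 partition = partition,
                 able = ev_able, able_closed = ev_able_cl,
                 surrogate = ev_pd, surrogate_closed = ev_pd_cl,
                 config = config, seed = seed),
            class = "experiment_report")
}

#' Tabulate peak-normalized RMS errors like a per-segment error table
#'
#' @param report an `experiment_report`.
#' @return data frame: group x plane rows, mean (SD) columns for the
#'   able-bodied-style and surrogate cohorts.
#' @export
rms_error_table <- function(report) {
  ch <- names(report$able$rms_mean)
  parts <- do.call(rbind, strsplit(ch, ".", fixed = TRUE))
  data.frame(group = parts[, 1], plane = parts[, 2],
             able_mean = unname(report$able$rms_mean),
             able_sd = unname(report$able$rms_sd),
             surrogate_mean = unname(report$surrogate$rms_mean),
             surrogate_sd = unname(report$surrogate$rms_sd))
}

#' @export
print.experiment_report <- function(x, digits = 3, ...) {
  cat("<experiment_report> master seed", x$seed, "\n")
  cat("  training:", x$train_report$stopping_epoch, "epochs (",
      x$train_report$reason, "), best epoch", x$train_report$best_epoch, "\n")
  cat("  pooled r (open loop): able-bodied style",
      round(x$able$pooled_r, digits), "| surrogate",
      round(x$surrogate$pooled_r, digits), "\n")
  if (!is.null(x$able_closed))
    cat("  pooled r (closed loop): able-bodied style",
        round(x$able_closed$pooled_r, digits), "| surrogate",
        round(x$surrogate_closed$pooled_r, digits), "\n")
  cat("  RMS error, % peak (able cohort): max",
      round(max(x$able$rms_mean), digits), "| mean",
      round(mean(x$able$rms_mean), digits), "\n")
  tab <- rms_error_table(x)
  tab$able <- sprintf("%.2f (%.2f)", tab$able_mean, tab$able_sd)
  tab$surrogate <- sprintf("%.2f (%.2f)", tab$surrogate_mean, tab$surrogate_sd)
  print(tab[, c("group", "plane", "able", "surrogate")], row.names = FALSE)
  invisible(x)
}
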