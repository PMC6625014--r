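# Virtual inertial measurement units: anatomically defined local sensor
# frames at the wrists, ankles and neck, gravity-inclusive accelerometer and
# gyroscope synthesis, Gaussian sensor noise and moving-average smoothing.

#' Sensor-frame construction rules for the five virtual IMUs
#'
#' Wrist sensors sit at the midpoint of the radial and ulnar styloid markers
#' with z toward the elbow joint center (epicondyle-marker midpoint) and y
#' toward the dorsal side of the hand. Ankle sensors sit at the malleolus
#' midpoint with z toward the knee joint center and y lateral. The neck
#' sensor sits at C7 with z toward the PSIS midpoint and y posterior in the
#' plane of C7, the PSIS midpoint and the jugular notch.
#'
#' Each rule lists `origin` markers (averaged), `z_to` markers (z axis points
#' from the origin toward their midpoint) and `y_hint` as a from/to marker
#' pair seeding the y direction. The z axis is exact; x = y_hint x z and
#' y = z x x, so the triad is exactly orthonormal even when the anatomical
#' y hint is not perpendicular to z.
#'
#' @return named list of specs for sensors `LW`, `RW`, `LA`, `RA`, `NK`.
#' @export
sensor_frame_specs <- function() {
  list(
    LW = list(origin = c("L_WR_A", "L_WR_B"),
              z_to = c("L_ELB_M", "L_ELB_L"),
              y_hint = list(from = "origin", to = "L_HND")),
    RW = list(origin = c("R_WR_A", "R_WR_B"),
              z_to = c("R_ELB_M", "R_ELB_L"),
              y_hint = list(from = "origin", to = "R_HND")),
    LA = list(origin = c("L_ANK_M", "L_ANK_L"),
              z_to = c("L_KNE_M", "L_KNE_L"),
              y_hint = list(from = "L_ANK_M", to = "L_ANK_L")),
    RA = list(origin = c("R_ANK_M", "R_ANK_L"),
              z_to = c("R_KNE_M", "R_KNE_L"),
              y_hint = list(from = "R_ANK_M", to = "R_ANK_L")),
    NK = list(origin = "C7",
              z_to = c("PSIS_L", "PSIS_R"),
              y_hint = list(from = "CLAV", to = "C7"))
  )
}

marker_mid <- function(markers, labels) {
  labs <- dimnames(markers)[[3]]
  miss <- setdiff(labels, labs)
  if (length(miss)) stop("missing marker(s): ", paste(miss, collapse = ", "))
  m <- markers[, , labels[1]]
  if (is.null(dim(m))) m <- matrix(markers[, , labels[1]], ncol = 3)
  if (length(labels) > 1)
    for (l in labels[-1]) m <- m + markers[, , l]
  m / length(labels)
}

#' Build a sensor frame series from markers
#'
#' @param markers frames x 3 x labels marker array.
#' @param spec one element of [sensor_frame_specs()].
#' @return list with `R` (3 x 3 x n local-to-lab, columns = x, y, z axes)
#'   and `origin` (n x 3, m).
#' @export
build_sensor_frame <- function(markers, spec) {
  origin <- marker_mid(markers, spec$origin)
  z_tgt <- marker_mid(markers, spec$z_to)
  z <- z_tgt - origin
  yh_from <- if (identical(spec$y_hint$from, "origin")) origin else
    marker_mid(markers, spec$y_hint$from)
  yh <- marker_mid(markers, spec$y_hint$to) - yh_from
  zn <- sqrt(rowSums(z^2))
  if (any(zn < 1e-9)) stop("degenerate geometry: z-axis target coincides with origin")
  z <- z / zn
  x <- cross3(yh, z)
  xn <- sqrt(rowSums(x^2))
  if (any(xn < 1e-9)) stop("degenerate geometry: y hint parallel to z axis")
  x <- x / xn
  y <- cross3(z, x)
  n <- nrow(origin)
  R <- array(0, c(3, 3, n))
  R[, 1, ] <- t(x); R[, 2, ] <- t(y); R[, 3, ] <- t(z)
  list(R = R, origin = origin)
}

#' Synthesize a noise-free virtual IMU signal
#'
#' The accelerometer reads specific force: the sensor-origin second
#' derivative minus gravity, rotated into the local frame, so a sensor at
#' rest reads +9.81 m/s^2 along the axis pointing up. The gyroscope reads
#' the frame angular velocity rotated into the local frame.
#'
#' @param frame list with `R` (3 x 3 x n) and `origin` (n x 3), as from
#'   [build_sensor_frame()].
#' @param dt sampling interval (s).
#' @param gravity lab-frame gravitational acceleration (m/s^2), default
#'   `c(0, 0, -9.81)`.
#' @return object of class `imu_signal`: n x 6 matrix with columns
#'   `ax, ay, az` (m/s^2) and `gx, gy, gz` (rad/s), all in the local frame.
#' @export
synthesize_imu <- function(frame, dt, gravity = c(0, 0, -9.81)) {
  n <- nrow(frame$origin)
  if (n < 5) stop("series too short to differentiate twice")
  acc_lab <- differentiate(differentiate(frame$origin, dt), dt)
  f_lab <- sweep(acc_lab, 2, gravity)          # specific force a - g
  w_lab <- angular_velocity(frame$R, dt)
  acc <- matrix(0, n, 3)
  gyr <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    Rt <- t(frame$R[, , i])
    acc[i, ] <- Rt %*% f_lab[i, ]
    gyr[i, ] <- Rt %*% w_lab[i, ]
  }
  out <- cbind(acc, gyr)
  colnames(out) <- c("ax", "ay", "az", "gx", "gy", "gz")
  structure(out, class = c("imu_signal", "matrix"), dt = dt,
            noisy = FALSE, smoothed = FALSE)
}

#' Sensor-noise specification
#'
#' Defaults follow typical low-cost IMU noise levels: accelerometer
#' sigma 0.15 m/s^2 and gyroscope sigma 0.005 rad/s, zero-mean Gaussian.
#'
#' @param accel_sigma accelerometer noise SD (m/s^2, >= 0).
#' @param gyro_sigma gyroscope noise SD (rad/s, >= 0).
#' @param seed integer seed for reproducible noise.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(accel_sigma = 0.15, gyro_sigma = 0.005, seed = 1L) {
  stopifnot(accel_sigma >= 0, gyro_sigma >= 0)
  structure(list(accel_sigma = accel_sigma, gyro_sigma = gyro_sigma,
                 seed = as.integer(seed)), class = "noise_spec")
}

#' Add Gaussian sensor noise to an IMU signal
#'
#' Adds iid zero-mean Gaussian noise per channel and frame; accelerometer
#' and gyroscope channels use their respective sigmas. Reproducible given
#' the seed in `spec`.
#'
#' @param signal an `imu_signal` (n x 6) or any n x (6k) matrix laid out as
#'   repeated `ax..az, gx..gz` blocks.
#' @param spec a [noise_spec()].
#' @return signal with noise added, same shape and class.
#' @export
add_imu_noise <- function(signal, spec) {
  stopifnot(inherits(spec, "noise_spec"), ncol(signal) %% 6 == 0)
  n <- nrow(signal)
  k <- ncol(signal) / 6
  sig <- rep(rep(c(spec$accel_sigma, spec$gyro_sigma), each = 3), k)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  noise <- matrix(stats::rnorm(n * ncol(signal)), n, ncol(signal))
  out <- signal + sweep(noise, 2, sig, `*`)
  attr(out, "noisy") <- TRUE
  out
}

#' Five-sensor 30-channel IMU stream for a trial
#'
#' Builds the five sensor frames from markers, synthesizes the six channels
#' per sensor and concatenates them sensor-major in the fixed order
#' LW, RW, LA, RA, NK x (ax, ay, az, gx, gy, gz).
#'
#' @param markers frames x 3 x labels marker array (m).
#' @param rate sampling rate (Hz).
#' @param noise optional [noise_spec()]; `NULL` (default) leaves the signal
#'   clean. Noise is injected before smoothing, as a real sensor's would be.
#' @param ma_window moving-average width in frames (default 5); `1` disables
#'   smoothing.
#' @return n x 30 matrix of class `imu_signal` with `sensor.channel`
#'   column names.
#' @export
imu_stream <- function(markers, rate = 100, noise = NULL, ma_window = 5) {
  specs <- sensor_frame_specs()
  dt <- 1 / rate
  sigs <- lapply(specs, function(sp)
    unclass(synthesize_imu(build_sensor_frame(markers, sp), dt)))
  out <- do.call(cbind, sigs)
  colnames(out) <- unlist(lapply(names(specs), function(s)
    paste(s, c("ax", "ay", "az", "gx", "gy", "gz"), sep = ".")))
  noisy <- FALSE
  if (!is.null(noise)) {
    out <- add_imu_noise(out, noise)
    noisy <- TRUE
  }
  out <- moving_average(out, ma_window)
  structure(out, class = c("imu_signal", "matrix"), dt = dt,
            noisy = noisy, smoothed = ma_window > 1)
}

#' @export
print.imu_signal <- function(x, ...) {
  cat("<imu_signal>", nrow(x), "frames x", ncol(x), "channels,",
      if (isTRUE(attr(x, "noisy"))) "noisy," else "clean,",
      if (isTRUE(attr(x, "smoothed"))) "smoothed\n" else "unsmoothed\n")
  invisible(x)
}
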