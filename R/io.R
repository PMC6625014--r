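# Text-format readers/writers: TRC marker trajectories, CSV exports for
# momentum traces and IMU streams.

#' Write marker trajectories to a TRC file
#'
#' Standard tab-separated TRC layout (header, marker-name row, X/Y/Z row,
#' then frame/time/coordinates), units meters.
#'
#' @param markers frames x 3 x labels array (m).
#' @param path output file.
#' @param rate sampling rate (Hz).
#' @export
write_trc <- function(markers, path, rate = 100) {
  n <- dim(markers)[1]
  labels <- dimnames(markers)[[3]]
  k <- length(labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("PathFileType", 4, "(X/Y/Z)", basename(path), sep = "\t"),
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"),
    paste(rate, rate, n, k, "m", rate, 1, n, sep = "\t"),
    paste0("Frame#\tTime\t", paste(labels, collapse = "\t\t\t")),
    paste0("\t\t", paste(unlist(lapply(seq_len(k), function(i)
      paste0(c("X", "Y", "Z"), i))), collapse = "\t"))), con)
  flat <- matrix(markers[, , 1], n, 3)   # x1 y1 z1 x2 y2 z2 ...
  for (i in seq_len(k)[-1]) flat <- cbind(flat, markers[, , i])
  dat <- cbind(seq_len(n), (seq_len(n) - 1) / rate, flat)
  utils::write.table(format(dat, trim = TRUE, digits = 10), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read marker trajectories from a TRC file
#'
#' @param path TRC file.
#' @return list with `markers` (frames x 3 x labels array, m) and `rate`
#'   (Hz).
#' @export
read_trc <- function(path) {
  head <- readLines(path, n = 5)
  meta <- strsplit(head[3], "\t")[[1]]
  rate <- as.numeric(meta[1])
  n <- as.integer(meta[3])
  k <- as.integer(meta[4])
  labels <- strsplit(head[4], "\t+")[[1]][-(1:2)][seq_len(k)]
  dat <- utils::read.table(path, skip = 5, sep = "\t", nrows = n)
  coords <- as.matrix(dat[, 2 + seq_len(3 * k)])
  markers <- array(0, c(n, 3, k), dimnames = list(NULL, NULL, labels))
  for (i in seq_len(k)) markers[, , i] <- coords[, 3 * (i - 1) + 1:3]
  list(markers = markers, rate = rate)
}

#' Write a momentum trace to CSV
#'
#' Columns: time (s) and the 15 `group.plane` momentum channels in the
#' body-aligned frame (sagittal = mediolateral axis, frontal = anterior
#' axis, transverse = vertical axis); a comment header documents the frame
#' convention and normalization.
#'
#' @param trace a `momentum_trace`.
#' @param path output file.
#' @export
write_momentum_csv <- function(trace, path) {
  dt <- attr(trace, "dt") %||% 0.01
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# segmental contributions to whole-body angular momentum",
    "# frame: moving body-aligned (vertical = lab vertical, anterior = trunk anterior projected horizontal)",
    paste0("# normalized by height*mass: ", isTRUE(attr(trace, "normalized")),
           " (height ", attr(trace, "height"), " m, mass ",
           attr(trace, "mass"), " kg)")), con)
  df <- data.frame(time = (seq_len(nrow(trace)) - 1) * dt, unclass(trace),
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a 30-channel IMU stream to CSV
#'
#' Channel ordering is sensor-major: LW, RW, LA, RA, NK x
#' (ax, ay, az, gx, gy, gz); accelerations m/s^2 (gravity-inclusive specific
#' force), angular velocities rad/s, local sensor frames.
#'
#' @param imu an `imu_signal` matrix.
#' @param path output file.
#' @export
write_imu_csv <- function(imu, path) {
  dt <- attr(imu, "dt") %||% 0.01
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# virtual IMU stream, sensor-major LW,RW,LA,RA,NK x (ax,ay,az,gx,gy,gz)",
    paste0("# noisy: ", isTRUE(attr(imu, "noisy")),
           ", smoothed: ", isTRUE(attr(imu, "smoothed")))), con)
  df <- data.frame(time = (seq_len(nrow(imu)) - 1) * dt, unclass(imu),
                   check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
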