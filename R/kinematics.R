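# Rigid-body kinematics primitives: least-squares pose fitting, numerical
# differentiation, angular-velocity extraction and zero-lag smoothing.

#' Least-squares rigid transform between two labeled point sets
#'
#' Finds the rotation `R` and translation `t` minimizing
#' \eqn{\sum_k \| R p_k + t - q_k \|^2} over all common labels (Kabsch /
#' orthogonal Procrustes via SVD), with the determinant sign fixed so that
#' `R` is a proper rotation.
#'
#' @param reference matrix (k x 3) of reference points, rownames = labels
#'   (or unlabeled, in which case rows are matched by position).
#' @param observed matrix (k x 3) of observed points, same labels.
#' @return list with `rotation` (3 x 3, `R`), `translation` (length 3, `t`)
#'   and `rmse`, the root-mean-square residual of the fit.
#' @examples
#' p <- cbind(c(0, 1, 0, 0), c(0, 0, 1, 0), c(0, 0, 0, 1))
#' fit <- rigid_fit(p, p)
#' max(abs(fit$rotation - diag(3)))  # identity recovered
#' @export
rigid_fit <- function(reference, observed) {
  reference <- as.matrix(reference)
  observed <- as.matrix(observed)
  if (!is.null(rownames(reference)) && !is.null(rownames(observed))) {
    common <- intersect(rownames(reference), rownames(observed))
    if (length(common) < 3) stop("need at least 3 common labeled markers")
    reference <- reference[common, , drop = FALSE]
    observed <- observed[common, , drop = FALSE]
  }
  if (nrow(reference) < 3 || nrow(reference) != nrow(observed))
    stop("need at least 3 common markers in both sets")
  cp <- colMeans(reference)
  cq <- colMeans(observed)
  P <- sweep(reference, 2, cp)
  Q <- sweep(observed, 2, cq)
  # collinearity check: second singular value of the centered cloud
  sv <- svd(P, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12))
    stop("degenerate marker geometry: points are (near-)collinear")
  H <- crossprod(P, Q)        # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cq - as.vector(R %*% cp)
  resid <- Q - P %*% t(R)
  list(rotation = R, translation = t,
       rmse = sqrt(mean(rowSums(resid^2))))
}

#' Differentiate a uniformly sampled signal
#'
#' Central differences on interior samples, one-sided differences at the two
#' ends; output has the same length as the input.
#'
#' @param x numeric vector or matrix (frames in rows).
#' @param dt sampling interval in seconds (> 0).
#' @return derivative, same shape as `x`.
#' @export
differentiate <- function(x, dt) {
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) stop("dt must be a positive scalar")
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 frames to differentiate")
  d <- x
  d[2:(n - 1), ] <- (x[3:n, , drop = FALSE] - x[1:(n - 2), , drop = FALSE]) / (2 * dt)
  d[1, ] <- (x[2, ] - x[1, ]) / dt
  d[n, ] <- (x[n, ] - x[n - 1, ]) / dt
  if (vec) d <- drop(d)
  d
}

#' Angular velocity from a rotation-matrix time series
#'
#' Differentiates the rotation series by central differences and extracts the
#' angular velocity from the skew-symmetric part of \eqn{\dot R R^\top},
#' returning the laboratory-frame angular velocity.
#'
#' @param R_series array (3 x 3 x n) of orthonormal local-to-lab rotations.
#' @param dt sampling interval (s).
#' @param tol orthonormality tolerance for input validation.
#' @return n x 3 matrix of angular velocity (rad/s, lab frame).
#' @export
angular_velocity <- function(R_series, dt, tol = 1e-6) {
  stopifnot(length(dim(R_series)) == 3, all(dim(R_series)[1:2] == 3))
  n <- dim(R_series)[3]
  if (n < 3) stop("need at least 3 frames")
  err <- max(abs(crossprod(R_series[, , 1]) - diag(3)),
             abs(crossprod(R_series[, , n]) - diag(3)))
  if (err > tol) stop("rotations are not orthonormal within tolerance")
  # flatten to n x 9 (column-major: R11,R21,R31,R12,...) and differentiate
  flat <- matrix(aperm(R_series, c(3, 1, 2)), nrow = n)
  dflat <- differentiate(flat, dt)
  # Omega = Rdot R^T; Omega[i,j] = sum_k Rdot[i,k] R[j,k], skew-symmetrized
  rowdot <- function(i, j)
    rowSums(dflat[, c(i, i + 3, i + 6), drop = FALSE] *
            flat[, c(j, j + 3, j + 6), drop = FALSE])
  cbind((rowdot(3, 2) - rowdot(2, 3)) / 2,
        (rowdot(1, 3) - rowdot(3, 1)) / 2,
        (rowdot(2, 1) - rowdot(1, 2)) / 2)
}

#' Zero-lag Butterworth low-pass smoothing
#'
#' Applies a Butterworth low-pass filter forward and backward
#' (zero-phase); the bidirectional pass doubles the effective order, so the
#' default `order = 4` follows the common motion-capture convention of a
#' "4th-order zero-lag" filter specified per pass. The signal is extended by
#' odd reflection at both ends before filtering to suppress edge transients.
#'
#' @param x numeric vector or matrix (frames in rows).
#' @param cutoff cutoff frequency (Hz).
#' @param rate sampling rate (Hz), must exceed `2 * cutoff`.
#' @param order filter order per pass (default 4).
#' @return smoothed signal, same shape as `x`.
#' @export
butterworth_smooth <- function(x, cutoff, rate, order = 4) {
  if (rate <= 2 * cutoff) stop("sampling rate must exceed twice the cutoff")
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  npad <- min(n - 1, max(3 * order, ceiling(10 * rate / cutoff)))
  if (npad < 3) stop("series too short for filter padding")
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  out <- x
  for (j in seq_len(ncol(x))) {
    s <- x[, j]
    # odd reflection about the end samples
    pre <- 2 * s[1] - s[(npad + 1):2]
    post <- 2 * s[n] - s[(n - 1):(n - npad)]
    ext <- c(pre, s, post)
    f <- signal::filtfilt(bf, ext)
    out[, j] <- f[(npad + 1):(npad + n)]
  }
  if (vec) out <- drop(out)
  out
}

#' Centered moving average with edge shrink
#'
#' Centered odd-width window; near the ends the window shrinks symmetrically
#' so the output has no phase shift and the same length as the input.
#'
#' @param x numeric vector or matrix (frames in rows).
#' @param window odd window width in frames (>= 1).
#' @return smoothed signal, same shape as `x`.
#' @export
moving_average <- function(x, window = 5) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (window > n) stop("window longer than signal")
  h <- (window - 1) / 2
  out <- x
  if (h > 0) {
    cs <- apply(x, 2, cumsum)
    cs <- rbind(0, cs)
    for (i in seq_len(n)) {
      k <- min(h, i - 1, n - i)   # symmetric shrink at edges
      out[i, ] <- (cs[i + k + 1, ] - cs[i - k, ]) / (2 * k + 1)
    }
  }
  if (vec) out <- drop(out)
  out
}
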