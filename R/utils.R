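# Small numeric helpers shared across modules.

#' Cross product of 3-vectors (rowwise for matrices)
#'
#' @param a,b numeric length-3 vectors, or n x 3 matrices (rowwise).
#' @return a x b, same shape as the inputs.
#' @keywords internal
cross3 <- function(a, b) {
  if (is.matrix(a)) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  } else {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }
}

# Rowwise normalization of an n x 3 matrix.
unit_rows <- function(m) m / sqrt(rowSums(m^2))

#' Elementary rotation matrices
#' @param theta angle in radians.
#' @return 3 x 3 rotation matrix.
#' @keywords internal
rot_x <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, s, 0, -s, c), 3, 3)
}

#' @rdname rot_x
#' @keywords internal
rot_y <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3)
}

#' @rdname rot_x
#' @keywords internal
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# C1-continuous ramp: 0 below a, 1 above b, cubic smoothstep between.
smoothstep <- function(x, a, b) {
  t <- pmin(pmax((x - a) / (b - a), 0), 1)
  t * t * (3 - 2 * t)
}

# Derive a child seed from a master seed; keeps results within 32-bit range.
derive_seed <- function(master, k) {
  as.integer((as.numeric(master) * 48271 + 1103 * as.numeric(k)) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
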