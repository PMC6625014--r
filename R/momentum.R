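# Segmental contributions to whole-body angular momentum about the body COM,
# expressed in a moving body-aligned frame, grouped into five momentum groups
# and normalized by subject height and mass.

#' One segment's contribution to whole-body angular momentum
#'
#' Computes the orbital-plus-spin contribution
#' \deqn{H_i = (r_i - r_{body}) \times m_i (v_i - v_{body}) + I_i \omega_i}
#' about the whole-body COM, in the laboratory frame. All arguments are
#' lab-frame quantities; `inertia` must be expressed in the lab frame at the
#' segment COM.
#'
#' @param r_i,v_i segment COM position (m) and velocity (m/s), length 3.
#' @param mass segment mass (kg).
#' @param inertia 3 x 3 segment inertia tensor (kg m^2, lab frame, at COM).
#' @param omega segment angular velocity (rad/s, lab frame), length 3.
#' @param r_body,v_body whole-body COM position and velocity, length 3.
#' @return length-3 angular momentum contribution (kg m^2/s, lab frame).
#' @examples
#' # point-mass-like segment: m = 2 kg at offset (1,0,0), relative velocity
#' # (0,3,0) -> H = (0,0,6)
#' segment_momentum(c(1, 0, 0), c(0, 3, 0), 2, diag(3) * 0, c(0, 0, 0),
#'                  c(0, 0, 0), c(0, 0, 0))
#' @export
segment_momentum <- function(r_i, v_i, mass, inertia, omega, r_body, v_body) {
  stopifnot(length(r_i) == 3, length(v_i) == 3, length(omega) == 3,
            all(dim(inertia) == c(3, 3)))
  cross3(r_i - r_body, mass * (v_i - v_body)) + as.vector(inertia %*% omega)
}

#' Per-segment angular-momentum time series
#'
#' Applies [segment_momentum()] across all frames and segments of a
#' [segment_states()] object. The segment inertia is rotated into the lab
#' frame per frame (\eqn{I_{lab} = R I_{local} R^\top}).
#'
#' @param states a `body_states` object.
#' @return named list per segment of n x 3 lab-frame momentum matrices
#'   (kg m^2/s).
#' @export
segment_momenta <- function(states) {
  stopifnot(inherits(states, "body_states"))
  out <- list()
  for (nm in names(states$segments)) {
    s <- states$segments[[nm]]
    rel_r <- s$com - states$r_body
    rel_v <- s$v - states$v_body
    H <- cross3(rel_r, s$mass * rel_v)
    for (i in seq_len(states$n)) {
      R <- s$R[, , i]
      H[i, ] <- H[i, ] + as.vector(R %*% (s$inertia_local %*% crossprod(R, s$omega[i, ])))
    }
    out[[nm]] <- H
  }
  out
}

#' Moving body-aligned reference frame
#'
#' Builds, per frame, the orthonormal triad with the vertical axis equal to
#' the lab vertical, the anterior axis equal to the trunk's anterior axis
#' projected into the horizontal plane (renormalized), and the mediolateral
#' axis their right-handed cross product (vertical x anterior).
#'
#' @param trunk_R 3 x 3 x n torso local-to-lab rotations (local +x anterior).
#' @return list with `anterior` and `mediolateral` (n x 3) and `vertical`
#'   (length 3, the lab vertical).
#' @export
body_frame <- function(trunk_R) {
  n <- dim(trunk_R)[3]
  ant <- t(trunk_R[, 1, ])           # trunk anterior axis in lab
  if (n == 1) ant <- matrix(trunk_R[, 1, 1], 1, 3)
  horiz <- sqrt(ant[, 1]^2 + ant[, 2]^2)
  if (any(horiz < sin(pi / 180)))
    stop("trunk anterior axis within 1 degree of vertical: body frame undefined")
  anterior <- cbind(ant[, 1] / horiz, ant[, 2] / horiz, 0)
  vertical <- c(0, 0, 1)
  ml <- cbind(-anterior[, 2], anterior[, 1], 0)   # vertical x anterior
  list(anterior = anterior, mediolateral = ml, vertical = vertical)
}

#' Re-express lab-frame momentum in the moving body frame
#'
#' Per-frame change of basis onto the body-aligned triad. Columns of the
#' result are the components about the mediolateral, anterior and vertical
#' axes, which are the sagittal-, frontal- and transverse-plane momenta
#' respectively.
#'
#' @param H n x 3 lab-frame momentum series.
#' @param frames a [body_frame()] result with matching length.
#' @return n x 3 matrix with columns `sagittal`, `frontal`, `transverse`.
#' @export
express_in_body_frame <- function(H, frames) {
  if (nrow(H) != nrow(frames$anterior))
    stop("momentum series and body-frame series have different lengths")
  out <- cbind(sagittal   = rowSums(H * frames$mediolateral),
               frontal    = rowSums(H * frames$anterior),
               transverse = H[, 3])
  out
}

#' Group segment momenta and normalize by height and mass
#'
#' Sums per-segment contributions into the five momentum groups and divides
#' by subject height times mass. Channels are group-major:
#' (left leg, right leg, left arm, right arm, trunk) x
#' (sagittal, frontal, transverse).
#'
#' @param H_segments named list of n x 3 body-frame momentum matrices, one
#'   per segment.
#' @param grouping named list mapping group name -> member segment names;
#'   default [momentum_groups()]. Every segment must belong to exactly one
#'   group.
#' @param height,mass subject stature (m) and mass (kg); normalization
#'   divides by `height * mass`. Pass `height = 1, mass = 1` for
#'   unnormalized traces.
#' @param dt sampling interval (s), stored with the trace.
#' @return object of class `momentum_trace`: an n x 15 matrix with
#'   `group.plane` column names plus normalization metadata.
#' @export
group_and_normalize <- function(H_segments, grouping = momentum_groups(),
                                height, mass, dt = 0.01) {
  assigned <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(assigned))
    stop("a segment is assigned to more than one group")
  miss <- setdiff(names(H_segments), assigned)
  if (length(miss))
    stop("segments not assigned to any group: ", paste(miss, collapse = ", "))
  n <- nrow(H_segments[[1]])
  out <- matrix(0, n, 3 * length(grouping))
  cn <- character(0)
  j <- 0
  for (g in names(grouping)) {
    Hg <- Reduce(`+`, H_segments[grouping[[g]]])
    out[, j + 1:3] <- Hg / (height * mass)
    cn <- c(cn, paste(g, c("sagittal", "frontal", "transverse"), sep = "."))
    j <- j + 3
  }
  colnames(out) <- cn
  structure(out, class = c("momentum_trace", "matrix"),
            normalized = !(height == 1 && mass == 1),
            height = height, mass = mass, dt = dt)
}

#' @export
print.momentum_trace <- function(x, ...) {
  cat("<momentum_trace>", nrow(x), "frames x", ncol(x), "channels",
      if (isTRUE(attr(x, "normalized"))) "(normalized by height*mass)" else "(raw kg m^2/s)",
      "\n")
  invisible(x)
}

#' Full momentum pipeline for one trial
#'
#' Markers -> zero-lag Butterworth smoothing -> rigid pose tracking ->
#' kinematic states -> per-segment momenta (lab) -> body-aligned frame ->
#' five-group normalized trace -> centered moving average.
#'
#' @param markers frames x 3 x labels marker array (m), or `NULL` to use
#'   `poses` directly.
#' @param model a [body_model()].
#' @param rate sampling rate (Hz).
#' @param poses optional precomputed poses (skips smoothing and fitting).
#' @param cutoff Butterworth cutoff (Hz) applied to markers.
#' @param ma_window moving-average width (frames) applied to the normalized
#'   trace.
#' @param normalize divide by height * mass (default TRUE).
#' @return a `momentum_trace`.
#' @export
momentum_trace <- function(markers = NULL, model, rate = 100, poses = NULL,
                           cutoff = 6, ma_window = 5, normalize = TRUE) {
  dt <- 1 / rate
  if (is.null(poses)) {
    if (is.null(markers)) stop("either markers or poses must be given")
    markers <- smooth_markers(markers, cutoff = cutoff, rate = rate)
    poses <- fit_segment_poses(markers, model)
  }
  states <- segment_states(poses, model, dt)
  H_lab <- segment_momenta(states)
  frames <- body_frame(states$segments$torso$R)
  H_body <- lapply(H_lab, express_in_body_frame, frames = frames)
  h <- if (normalize) model$height else 1
  m <- if (normalize) model$mass else 1
  trace <- group_and_normalize(H_body, height = h, mass = m, dt = dt)
  sm <- moving_average(unclass(trace), ma_window)
  attributes(sm) <- attributes(trace)
  sm
}

#' Smooth a marker array with the zero-lag Butterworth filter
#' @param markers frames x 3 x labels array.
#' @inheritParams butterworth_smooth
#' @return smoothed array, same shape.
#' @export
smooth_markers <- function(markers, cutoff = 6, rate = 100, order = 4) {
  d <- dim(markers)
  flat <- matrix(markers, nrow = d[1])
  sm <- butterworth_smooth(flat, cutoff = cutoff, rate = rate, order = order)
  array(sm, dim = d, dimnames = dimnames(markers))
}
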