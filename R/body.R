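# Twelve-segment body model: segment geometry scaled from stature, marker
# templates fixed in segment frames, least-squares pose tracking and
# differentiation into full kinematic segment states.

SEGMENT_BASES <- c(pelvis = "pelvis", torso = "torso",
                   L_upper_arm = "upper_arm", R_upper_arm = "upper_arm",
                   L_forearm = "forearm", R_forearm = "forearm",
                   L_thigh = "thigh", R_thigh = "thigh",
                   L_shank = "shank", R_shank = "shank",
                   L_foot = "foot", R_foot = "foot")

# Default mapping of the 12 tracked segments onto the 5 reported momentum
# groups: leg = thigh+shank+foot, arm = upper arm+forearm (hand folded in),
# trunk = torso+pelvis (head folded into torso).
#' Default segment-to-group mapping
#' @return named list: momentum group -> character vector of segment names.
#' @export
momentum_groups <- function() {
  list(left_leg  = c("L_thigh", "L_shank", "L_foot"),
       right_leg = c("R_thigh", "R_shank", "R_foot"),
       left_arm  = c("L_upper_arm", "L_forearm"),
       right_arm = c("R_upper_arm", "R_forearm"),
       trunk     = c("torso", "pelvis"))
}

# Marker template for one segment: k x 3 local coordinates, rownames are the
# final (side-prefixed) marker labels. sgn = +1 left, -1 right.
marker_template <- function(base, side, L, geom) {
  sgn <- if (identical(side, "R")) -1 else 1
  pre <- if (is.null(side)) "" else paste0(side, "_")
  m <- switch(base,
    pelvis = rbind(
      PSIS_L = c(-0.08,  0.06, 0.02),
      PSIS_R = c(-0.08, -0.06, 0.02),
      ASIS_L = c( 0.08,  0.09, 0.01),
      ASIS_R = c( 0.08, -0.09, 0.01),
      SACR   = c(-0.10,  0.00, 0.06)),
    torso = rbind(
      C7    = c(-0.05, 0, L),
      CLAV  = c( 0.05, 0, L - 0.02),
      T10   = c(-0.06, 0, 0.40 * L),
      STRN  = c( 0.06, 0, 0.45 * L),
      SHO_L = c( 0.00,  geom$shoulder_width / 2, L),
      SHO_R = c( 0.00, -geom$shoulder_width / 2, L)),
    upper_arm = rbind(
      ELB_M = c( 0.00, -sgn * 0.035, -L),
      ELB_L = c( 0.00,  sgn * 0.035, -L),
      UPA1  = c( 0.04,  0.00,        -0.30 * L),
      UPA2  = c(-0.03,  sgn * 0.030, -0.55 * L)),
    forearm = rbind(
      WR_A = c( 0.00,  sgn * 0.030, -L),       # radial styloid
      WR_B = c( 0.00, -sgn * 0.030, -L),       # ulnar styloid
      HND  = c( 0.05,  0.00,        -L - 0.04), # dorsal hand
      FRA1 = c( 0.03,  0.00,        -0.30 * L),
      FRA2 = c(-0.02,  sgn * 0.025, -0.60 * L)),
    thigh = rbind(
      KNE_M = c( 0.00, -sgn * 0.050, -L),
      KNE_L = c( 0.00,  sgn * 0.050, -L),
      THI1  = c( 0.05,  0.00,        -0.30 * L),
      THI2  = c(-0.04,  sgn * 0.030, -0.60 * L)),
    shank = rbind(
      ANK_M = c( 0.00, -sgn * 0.040, -L),
      ANK_L = c( 0.00,  sgn * 0.040, -L),
      TIB1  = c( 0.04,  0.00,        -0.30 * L),
      TIB2  = c(-0.03,  sgn * 0.030, -0.60 * L)),
    foot = rbind(
      HEE = c(-0.25 * L, 0.00,        -0.070),
      TOE = c( 0.75 * L, 0.00,        -0.055),
      MT1 = c( 0.50 * L, -sgn * 0.040, -0.045),
      MT5 = c( 0.45 * L,  sgn * 0.050, -0.060)),
    stop("unknown segment base '", base, "'"))
  rownames(m) <- paste0(pre, rownames(m))
  m
}

#' Build a scaled 12-segment body model
#'
#' Scales segment lengths from stature, derives segment masses, COM offsets
#' and local inertia tensors from the anthropometric table, and attaches the
#' marker template (four or more markers rigid in each segment frame,
#' including the named landmarks used by the virtual-sensor frames: wrist
#' styloids, malleoli, femoral/humeral epicondyles, C7, PSIS, jugular notch,
#' dorsal hand).
#'
#' Local frames: +x anterior, +y subject-left, +z up at neutral pose.
#' Limb segments have their long axis along local -z with the origin at the
#' proximal joint; pelvis and torso have +z up; the foot's long axis is +x
#' with the origin at the ankle.
#'
#' @param height subject stature (m).
#' @param mass subject mass (kg).
#' @param table an [anthropometric_table()]; default bundled table.
#' @return object of class `body_model`.
#' @export
body_model <- function(height, mass, table = anthropometric_table()) {
  stopifnot(height > 0, mass > 0)
  geom <- list(hip_width = 0.17 * height,
               shoulder_width = 0.245 * height,
               hip_height = 0.530 * height)
  segs <- list()
  for (nm in names(SEGMENT_BASES)) {
    base <- SEGMENT_BASES[[nm]]
    side <- if (grepl("^[LR]_", nm)) substr(nm, 1, 1) else NULL
    L <- table[[base]]$length_fraction * height
    inr <- segment_inertia(table, base, L, mass)
    if (base == "foot") {
      # long axis is +x: COM along x from the ankle origin (ankle sits about
      # a quarter of foot length from the heel), small radius along x
      com_local <- c((inr$com_fraction - 0.25) * L, 0, -0.04)
      k <- diag(inr$inertia)
      inertia <- diag(k[c(3, 2, 1)])
    } else if (base %in% c("pelvis", "torso")) {
      com_local <- c(0, 0, inr$com_fraction * L)
      inertia <- inr$inertia
    } else {
      com_local <- c(0, 0, -inr$com_fraction * L)
      inertia <- inr$inertia
    }
    segs[[nm]] <- list(name = nm, base = base, side = side, length = L,
                       mass = inr$mass, com_local = com_local,
                       inertia_local = inertia,
                       markers = marker_template(base, side, L, geom))
  }
  structure(list(height = height, mass = mass, geometry = geom,
                 segments = segs, table = table),
            class = "body_model")
}

#' @export
print.body_model <- function(x, ...) {
  cat("<body_model> 12 segments, height", x$height, "m, mass", x$mass, "kg\n")
  cat("  modeled mass:", round(sum(vapply(x$segments, `[[`, 0, "mass")), 3), "kg\n")
  invisible(x)
}

#' Track segment poses from marker trajectories
#'
#' Fits, per frame and per segment, the least-squares rigid transform from
#' the segment's marker template (local coordinates) to the observed marker
#' positions, giving the local-to-lab rotation and the lab position of the
#' segment origin.
#'
#' @param markers array (frames x 3 x labels) of marker positions (m), with
#'   `dimnames[[3]]` the marker labels.
#' @param model a [body_model()].
#' @return named list per segment: `R` (3 x 3 x n) and `origin` (n x 3).
#' @export
fit_segment_poses <- function(markers, model) {
  n <- dim(markers)[1]
  labels <- dimnames(markers)[[3]]
  poses <- list()
  for (nm in names(model$segments)) {
    tmpl <- model$segments[[nm]]$markers
    miss <- setdiff(rownames(tmpl), labels)
    if (length(miss))
      stop("markers missing for segment ", nm, ": ", paste(miss, collapse = ", "))
    obs <- markers[, , rownames(tmpl), drop = FALSE]
    poses[[nm]] <- fit_pose_series(tmpl, obs)
  }
  poses
}

# Per-frame Kabsch fit against a fixed template: the template centroid and
# collinearity check are hoisted out of the frame loop.
fit_pose_series <- function(template, obs) {
  n <- dim(obs)[1]
  k <- nrow(template)
  cp <- colMeans(template)
  P <- sweep(template, 2, cp)
  sv <- svd(P, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-12))
    stop("degenerate marker template: points are (near-)collinear")
  R <- array(0, c(3, 3, n))
  origin <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    q <- matrix(obs[i, , ], 3, k)
    cq <- rowMeans(q)
    H <- (q - cq) %*% P                 # 3x3, sum of q_c p_c^T
    s <- svd(H)
    d <- sign(det(s$u %*% t(s$v)))
    Ri <- s$u %*% (c(1, 1, d) * t(s$v))
    R[, , i] <- Ri
    origin[i, ] <- cq - as.vector(Ri %*% cp)
  }
  list(R = R, origin = origin)
}

#' Differentiate segment poses into full kinematic states
#'
#' Computes per-segment COM positions, velocities, accelerations and
#' angular velocities, plus the whole-body COM position and velocity
#' (mass-weighted means over the modeled segments).
#'
#' @param poses per-segment list of `R` (3 x 3 x n) and `origin` (n x 3), as
#'   from [fit_segment_poses()] or a synthetic trial's ground truth.
#' @param model a [body_model()].
#' @param dt sampling interval (s).
#' @return object of class `body_states`: per-segment kinematics, `r_body`,
#'   `v_body`, time step and subject size.
#' @export
segment_states <- function(poses, model, dt) {
  n <- dim(poses[[1]]$R)[3]
  states <- list()
  masses <- vapply(model$segments, `[[`, 0, "mass")
  r_body <- matrix(0, n, 3)
  for (nm in names(model$segments)) {
    seg <- model$segments[[nm]]
    p <- poses[[nm]]
    com <- p$origin
    for (i in seq_len(n))
      com[i, ] <- p$origin[i, ] + as.vector(p$R[, , i] %*% seg$com_local)
    v <- differentiate(com, dt)
    a <- differentiate(v, dt)
    w <- angular_velocity(p$R, dt)
    states[[nm]] <- list(R = p$R, origin = p$origin, com = com, v = v, a = a,
                         omega = w, mass = seg$mass,
                         inertia_local = seg$inertia_local)
    r_body <- r_body + seg$mass * com
  }
  total_mass <- sum(masses)
  r_body <- r_body / total_mass
  v_body <- Reduce(`+`, lapply(states, function(s) s$mass * s$v)) / total_mass
  structure(list(segments = states, r_body = r_body, v_body = v_body,
                 dt = dt, n = n, total_mass = total_mass,
                 height = model$height, mass = model$mass),
            class = "body_states")
}
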