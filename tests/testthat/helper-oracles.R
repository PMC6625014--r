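# Independent oracles used by the tests: quaternion kinematics, point-cloud
# momentum, and a torque-free rigid-body integrator. These deliberately do
# not share code with the package implementation.

# --- quaternions (w, x, y, z), scalar-first ---------------------------------

quat_mul <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] + c(a[3] * b[4] - a[4] * b[3],
                                      a[4] * b[2] - a[2] * b[4],
                                      a[2] * b[3] - a[3] * b[2]))
}

quat_to_mat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

axis_angle_quat <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# Rotation series about a fixed axis at constant rate (rad/s).
spin_series <- function(axis, rate, n, dt) {
  R <- array(0, c(3, 3, n))
  for (i in seq_len(n))
    R[, , i] <- quat_to_mat(axis_angle_quat(axis, rate * (i - 1) * dt))
  R
}

# Lab angular velocity from a quaternion series: omega = 2 * (dq/dt) * q^-1.
quat_omega <- function(q_series, dt) {
  n <- nrow(q_series)
  w <- matrix(0, n, 3)
  for (i in 2:(n - 1)) {
    dq <- (q_series[i + 1, ] - q_series[i - 1, ]) / (2 * dt)
    qi <- q_series[i, ] * c(1, -1, -1, -1)   # conjugate of a unit quaternion
    w[i, ] <- 2 * quat_mul(dq, qi)[2:4]
  }
  w
}

# --- point-cloud angular momentum oracle ------------------------------------

# Six point masses reproducing a rigid body's mass, COM and diagonal local
# inertia: pairs at +-d_j along each local axis with mass m/6 each.
segment_point_cloud <- function(mass, inertia_diag) {
  I <- inertia_diag
  d2 <- 3 / (2 * mass) * c(I[2] + I[3] - I[1],
                           I[1] + I[3] - I[2],
                           I[1] + I[2] - I[3])
  d <- sqrt(pmax(d2, 0))
  pts <- rbind(c(d[1], 0, 0), c(-d[1], 0, 0),
               c(0, d[2], 0), c(0, -d[2], 0),
               c(0, 0, d[3]), c(0, 0, -d[3]))
  list(points = pts, masses = rep(mass / 6, 6))
}

# Whole-body angular momentum about the pooled-particle COM at one frame,
# computed from point particles only (v_p = v_com + omega x (r_p - r_com)).
pointcloud_momentum <- function(states, frame) {
  r_all <- NULL; v_all <- NULL; m_all <- NULL
  for (s in states$segments) {
    pc <- segment_point_cloud(s$mass, diag(s$inertia_local))
    R <- s$R[, , frame]
    for (k in 1:6) {
      rp <- s$com[frame, ] + as.vector(R %*% pc$points[k, ])
      vp <- s$v[frame, ] + c(s$omega[frame, 2] * (rp - s$com[frame, ])[3] -
                               s$omega[frame, 3] * (rp - s$com[frame, ])[2],
                             s$omega[frame, 3] * (rp - s$com[frame, ])[1] -
                               s$omega[frame, 1] * (rp - s$com[frame, ])[3],
                             s$omega[frame, 1] * (rp - s$com[frame, ])[2] -
                               s$omega[frame, 2] * (rp - s$com[frame, ])[1])
      r_all <- rbind(r_all, rp); v_all <- rbind(v_all, vp)
      m_all <- c(m_all, pc$masses[k])
    }
  }
  rc <- colSums(r_all * m_all) / sum(m_all)
  vc <- colSums(v_all * m_all) / sum(m_all)
  H <- c(0, 0, 0)
  for (k in seq_along(m_all)) {
    dr <- r_all[k, ] - rc; dv <- m_all[k] * (v_all[k, ] - vc)
    H <- H + c(dr[2] * dv[3] - dr[3] * dv[2],
               dr[3] * dv[1] - dr[1] * dv[3],
               dr[1] * dv[2] - dr[2] * dv[1])
  }
  H
}

# --- torque-free rigid body (Euler equations, RK4 on body rates + quaternion)

free_body_trajectory <- function(I_diag, omega0_body, q0, r0, v0, n, dt) {
  q <- q0; wb <- omega0_body
  Rs <- array(0, c(3, 3, n)); origins <- matrix(0, n, 3)
  deriv <- function(state) {
    q <- state[1:4]; w <- state[5:7]
    dq <- 0.5 * quat_mul(q, c(0, w))
    dw <- c((I_diag[2] - I_diag[3]) * w[2] * w[3] / I_diag[1],
            (I_diag[3] - I_diag[1]) * w[3] * w[1] / I_diag[2],
            (I_diag[1] - I_diag[2]) * w[1] * w[2] / I_diag[3])
    c(dq, dw)
  }
  state <- c(q, wb)
  for (i in seq_len(n)) {
    qn <- state[1:4] / sqrt(sum(state[1:4]^2))
    Rs[, , i] <- quat_to_mat(qn)
    origins[i, ] <- r0 + v0 * (i - 1) * dt
    k1 <- deriv(state)
    k2 <- deriv(state + dt / 2 * k1)
    k3 <- deriv(state + dt / 2 * k2)
    k4 <- deriv(state + dt * k3)
    state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  list(R = Rs, origin = origins)
}

# --- small fixtures ---------------------------------------------------------

tiny_circuit <- function(length = 3, speed = 1.1)
  circuit_spec(segments = list(list(type = "level", length = length)),
               speed = speed)

tiny_trial <- function(seed = 1, ...)
  generate_trial(tiny_circuit(), gait_style(...),
                 subject = list(height = 1.75, mass = 70), seed = seed)
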