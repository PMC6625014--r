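# Segmental angular momentum: the orbital + spin decomposition, the moving
# body-aligned frame, grouping/normalization, and the physical invariants
# (superposition against a point-cloud oracle, conservation for a free-
# floating system).

test_that("segment_momentum reproduces hand-computed cases", {
  z3 <- c(0, 0, 0)
  # coincident COMs, zero spin
  expect_equal(segment_momentum(c(1, 1, 1), c(2, 0, 0), 3, diag(3) * 0.1, z3,
                                c(1, 1, 1), c(2, 0, 0)), z3)
  # point-mass cross product: m=2 at offset (1,0,0), rel. velocity (0,3,0)
  expect_equal(segment_momentum(c(1, 0, 0), c(0, 3, 0), 2, diag(3) * 0, z3,
                                z3, z3), c(0, 0, 6))
  # pure spin: I = diag(0.1, 0.2, 0.3), omega = (1,1,1)
  expect_equal(segment_momentum(z3, z3, 5, diag(c(0.1, 0.2, 0.3)),
                                c(1, 1, 1), z3, z3), c(0.1, 0.2, 0.3))
})

test_that("summed segment momenta match the point-cloud oracle (superposition)", {
  tr <- tiny_trial(seed = 9)
  states <- segment_states(tr$poses, tr$model, 1 / tr$rate)
  H_segs <- segment_momenta(states)
  H_sum <- Reduce(`+`, H_segs)
  for (frame in c(10, 60, 120)) {
    H_oracle <- pointcloud_momentum(states, frame)
    expect_lt(sqrt(sum((H_sum[frame, ] - H_oracle)^2)) /
                sqrt(sum(H_oracle^2)), 1e-9)
  }
})

test_that("lab-frame H is conserved for a free-floating system", {
  # three torque-free tumbling bodies, gravity off, no contact, 2 s
  dt <- 1e-3; n <- 2001
  bodies <- list(
    list(I = c(0.10, 0.20, 0.30), w = c(1.2, 0.3, -0.5), r = c(0, 0, 0),
         v = c(0.2, 0, 0), m = 4),
    list(I = c(0.05, 0.05, 0.09), w = c(-0.5, 2.0, 0.4), r = c(1, 0, 0),
         v = c(-0.1, 0.3, 0), m = 2),
    list(I = c(0.02, 0.04, 0.05), w = c(0.8, -1.0, 1.5), r = c(0, 1, 1),
         v = c(0, -0.2, 0.1), m = 1))
  segs <- list()
  for (b in bodies) {
    traj <- free_body_trajectory(b$I, b$w, c(1, 0, 0, 0), b$r, b$v, n, dt)
    com <- traj$origin
    segs[[paste0("body", length(segs) + 1)]] <- list(
      R = traj$R, com = com, v = differentiate(com, dt),
      omega = angular_velocity(traj$R, dt), mass = b$m,
      inertia_local = diag(b$I))
  }
  masses <- vapply(segs, `[[`, 0, "mass")
  r_body <- Reduce(`+`, lapply(segs, function(s) s$mass * s$com)) / sum(masses)
  v_body <- Reduce(`+`, lapply(segs, function(s) s$mass * s$v)) / sum(masses)
  states <- structure(list(segments = segs, r_body = r_body, v_body = v_body,
                           dt = dt, n = n), class = "body_states")
  H <- Reduce(`+`, segment_momenta(states))
  interior <- 10:(n - 10)
  magnitudes <- sqrt(rowSums(H[interior, ]^2))
  drift <- (max(magnitudes) - min(magnitudes)) / stats::median(magnitudes)
  expect_lt(drift, 0.005)
})

test_that("body_frame follows the trunk heading and flags degeneracy", {
  Rs <- array(diag(3), c(3, 3, 3))
  bf <- body_frame(Rs)
  expect_equal(bf$anterior[1, ], c(1, 0, 0))
  expect_equal(bf$mediolateral[1, ], c(0, 1, 0))

  # anterior (1,0,1)/sqrt(2) projects to (1,0,0)
  Rtilt <- array(quat_to_mat(axis_angle_quat(c(0, 1, 0), -pi / 4)), c(3, 3, 1))
  expect_equal(body_frame(Rtilt)$anterior[1, ], c(1, 0, 0))

  Rup <- array(quat_to_mat(axis_angle_quat(c(0, 1, 0), -pi / 2)), c(3, 3, 1))
  expect_error(body_frame(Rup), "vertical")
})

test_that("body-frame re-expression is an isometry matching a rotation oracle", {
  n <- 50
  yaw <- seq(0, pi / 6, length.out = n)    # trunk rotated up to 30 degrees
  Rs <- array(0, c(3, 3, n))
  for (i in seq_len(n)) Rs[, , i] <- quat_to_mat(axis_angle_quat(c(0, 0, 1), yaw[i]))
  frames <- body_frame(Rs)
  set.seed(3)
  H <- matrix(rnorm(3 * n), n, 3)
  Hb <- express_in_body_frame(H, frames)
  expect_equal(sqrt(rowSums(Hb^2)), sqrt(rowSums(H^2)), tolerance = 1e-12)
  # oracle: components about (ml, ant, vert) equal lab H rotated by -yaw
  for (i in c(1, 25, 50)) {
    Hrot <- as.vector(t(quat_to_mat(axis_angle_quat(c(0, 0, 1), yaw[i]))) %*% H[i, ])
    expect_equal(unname(Hb[i, ]), Hrot[c(2, 1, 3)], tolerance = 1e-10)
  }
  expect_error(express_in_body_frame(H[1:10, ], frames), "length")
})

test_that("grouping sums members, normalizes, and preserves superposition", {
  n <- 20
  set.seed(4)
  segs <- setNames(lapply(1:4, function(i) matrix(rnorm(3 * n), n, 3)),
                   c("a", "b", "c", "d"))
  grouping <- list(g1 = c("a", "b"), g2 = "c", g3 = "d")
  tr <- group_and_normalize(segs, grouping, height = 1, mass = 1)
  expect_equal(unclass(tr)[, 1:3], segs$a + segs$b, ignore_attr = TRUE)
  expect_equal(unclass(tr)[, 4:6], segs$c, ignore_attr = TRUE)
  expect_false(attr(tr, "normalized"))

  trn <- group_and_normalize(segs, grouping, height = 1.8, mass = 70)
  expect_equal(unclass(trn) * 1.8 * 70, unclass(tr), ignore_attr = TRUE)
  # superposition: the group traces sum to the normalized whole-body H
  whole <- Reduce(`+`, segs) / (1.8 * 70)
  expect_equal(unclass(trn)[, 1:3] + unclass(trn)[, 4:6] + unclass(trn)[, 7:9],
               whole, ignore_attr = TRUE)

  expect_error(group_and_normalize(segs, list(g1 = c("a", "b"), g2 = "c"),
                                   height = 1, mass = 1), "not assigned")
})

test_that("full momentum pipeline from markers matches the ground-truth-pose route", {
  tr <- tiny_trial(seed = 12)
  via_markers <- momentum_trace(markers = tr$markers, model = tr$model,
                                rate = tr$rate)
  via_poses <- momentum_trace(poses = tr$poses, model = tr$model,
                              rate = tr$rate)
  n <- nrow(via_markers)
  interior <- 30:(n - 30)   # away from filter edge effects
  rel <- sqrt(mean((via_markers[interior, ] - via_poses[interior, ])^2)) /
    stats::sd(via_poses[interior, ])
  expect_lt(rel, 0.01)
})
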