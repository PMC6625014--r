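# Synthetic gait generator: kinematic consistency, determinism, the circuit
# schedule, and the perturbed-gait surrogate.

test_that("zero amplitudes and zero speed give a stationary standing posture", {
  still <- gait_style(hip_amp = 0, knee_amp = 0, ankle_amp = 0,
                      arm_swing = 0, trunk_twist = 0, pelvis_roll = 0,
                      sway = 0, bob = 0, jitter = 0)
  tr <- generate_trial(tiny_circuit(speed = 1e-9), still,
                       subject = list(height = 1.75, mass = 70), seed = 1)
  moves <- apply(tr$markers, c(2, 3), function(x) diff(range(x)))
  expect_lt(max(moves), 1e-6)
})

test_that("level walking covers speed x time along the path", {
  tr <- generate_trial(circuit_spec(segments = list(list(type = "level",
                                                         length = 12)),
                                    speed = 1.2),
                       gait_style(jitter = 0),
                       subject = list(height = 1.75, mass = 70), seed = 2)
  root <- tr$poses$pelvis$origin
  disp <- sqrt(sum((root[nrow(root), 1:2] - root[1, 1:2])^2))
  expect_equal(disp, 12, tolerance = 0.2)
  expect_equal(tr$duration, 10, tolerance = 0.1)
})

test_that("trials are bitwise reproducible by seed", {
  a <- tiny_trial(seed = 33)
  b <- tiny_trial(seed = 33)
  expect_identical(a$markers, b$markers)
  c <- tiny_trial(seed = 34)
  expect_false(identical(a$markers, c$markers))
})

test_that("markers are rigid in segment frames (pre-jitter consistency)", {
  tr <- tiny_trial(seed = 7)
  for (nm in c("L_forearm", "R_shank", "torso")) {
    seg <- tr$model$segments[[nm]]
    p <- tr$poses[[nm]]
    for (i in c(1, 50, 101)) {
      rebuilt <- t(p$R[, , i] %*% t(seg$markers) + p$origin[i, ])
      expect_lt(max(abs(rebuilt - t(tr$markers[i, , rownames(seg$markers)]))),
                1e-12)
    }
  }
})

test_that("the default circuit produces 10-12 s trials with all task labels", {
  tr <- generate_trial(seed = 10)
  expect_gt(tr$duration, 9.5); expect_lt(tr$duration, 13)
  expect_setequal(unique(tr$labels), c("level", "stair", "turn", "ramp"))
})

test_that("infeasible speed/cadence combinations are rejected", {
  expect_error(generate_trial(circuit_spec(speed = 4, cadence = 40),
                              gait_style(jitter = 0)), "infeasible")
  expect_error(circuit_spec(segments = list(list(type = "stairs", n_steps = 2,
                                                 rise = 0.5, run = 0.3,
                                                 direction = "up"))),
               "rise")
})

test_that("cohorts follow the start-point and lead-leg schedule", {
  co <- make_cohort(4, circuit = tiny_circuit(), seed = 3)
  expect_equal(vapply(co$trials, function(t) t$circuit$start, ""),
               c("A", "B", "A", "B"))
  expect_equal(vapply(co$trials, function(t) t$circuit$lead_leg, ""),
               c("L", "L", "R", "R"))
  # profiles cycle: 10 trials over 5 profiles = 2 each
  co10 <- make_cohort(10, circuit = tiny_circuit(), seed = 3)
  heights <- vapply(co10$trials, function(t) t$subject$height, 0)
  expect_equal(unname(table(heights)), rep(2L, 5), ignore_attr = TRUE)
})

test_that("steady walking yields near-periodic momentum at the stride period", {
  tr <- generate_trial(circuit_spec(segments = list(list(type = "level",
                                                         length = 8)),
                                    speed = 1.1, cadence = 110),
                       gait_style(jitter = 0),
                       subject = list(height = 1.75, mass = 70), seed = 5)
  trc <- momentum_trace(poses = tr$poses, model = tr$model, rate = tr$rate)
  x <- trc[, "left_leg.sagittal"]
  stride <- round(tr$rate * 120 / 110)   # frames per stride
  interior <- 100:(length(x) - stride - 50)
  r <- stats::cor(x[interior], x[interior + stride])
  expect_gt(r, 0.9)
})

test_that("pd_surrogate perturbs the style as documented", {
  base <- gait_style()
  same <- pd_surrogate(base, arm_swing_factor = 1, asymmetry = 1,
                       speed_factor = 1, tremor_amp = 0)
  expect_equal(same, base)
  pd <- pd_surrogate(base)
  expect_equal(pd$arm_swing, 0.6 * base$arm_swing)
  expect_equal(pd$asymmetry, 0.8)
  expect_equal(pd$speed_factor, 0.85)
})

test_that("the surrogate cohort is more asymmetric in arm momentum", {
  asym_index <- function(style, seed) {
    tr <- generate_trial(tiny_circuit(length = 5), style,
                         subject = list(height = 1.75, mass = 70), seed = seed)
    trc <- momentum_trace(poses = tr$poses, model = tr$model, rate = tr$rate)
    diff(range(trc[, "right_arm.sagittal"])) /
      diff(range(trc[, "left_arm.sagittal"]))
  }
  base <- mean(vapply(1:3, function(s) asym_index(gait_style(jitter = 0), s), 0))
  pd <- mean(vapply(1:3, function(s)
    asym_index(pd_surrogate(gait_style(jitter = 0)), s), 0))
  # the base cohort is left/right symmetric (index near 1); the surrogate's
  # unequal arm swing moves the index away from symmetry
  expect_gt(abs(pd - 1), abs(base - 1) + 0.05)
})
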