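# Kinematic articulated-gait generator: a 12-segment walker driven by
# phase-locked periodic joint patterns whose pelvis follows a configurable
# locomotor circuit (level ground, stairs, ramp, turns). Purely kinematic --
# Eq.-style momentum computation needs only kinematics plus inertia -- with
# no claim of physiological fidelity beyond gait-like signal bandwidth.

#' Locomotor-circuit specification
#'
#' The default circuit emulates a non-steady-state protocol: level walking,
#' a 4-step staircase (rise 0.15 m, run 0.30 m), a 180-degree turn and a
#' 2.5 m ramp at 10 degrees, walked from start point A to B; starting from B
#' traverses the same tasks in reverse (stairs descended, ramp ascended).
#'
#' @param segments list of path segments; each is a list with `type` one of
#'   `"level"` (`length` m), `"stairs"` (`n_steps`, `rise` m, `run` m,
#'   `direction` "up"/"down"), `"ramp"` (`length` m, `incline` degrees,
#'   signed), `"turn"` (`angle` degrees, signed, `radius` m).
#' @param speed walking speed along the path (m/s).
#' @param cadence step rate (steps/min).
#' @param start `"A"` (forward) or `"B"` (circuit reversed).
#' @param rate sampling rate (Hz).
#' @return object of class `circuit_spec`.
#' @export
circuit_spec <- function(segments = NULL, speed = 1.1, cadence = 110,
                         start = "A", rate = 100) {
  if (is.null(segments)) {
    segments <- list(
      list(type = "level", length = 3.0),
      list(type = "stairs", n_steps = 4, rise = 0.15, run = 0.30,
           direction = "up"),
      list(type = "level", length = 0.6),
      list(type = "turn", angle = 180, radius = 0.9),
      list(type = "ramp", length = 2.5, incline = -10),
      list(type = "level", length = 3.0))
  }
  for (s in segments) {
    if (identical(s$type, "stairs") && s$rise > 0.3)
      stop("stair rise exceeds 0.3 m")
    if (identical(s$type, "ramp") && abs(s$incline) > 20)
      stop("ramp incline exceeds 20 degrees")
  }
  stopifnot(speed > 0, cadence > 0, rate > 0, start %in% c("A", "B"))
  if (start == "B") {
    segments <- rev(lapply(segments, function(s) {
      if (s$type == "stairs")
        s$direction <- if (s$direction == "up") "down" else "up"
      if (s$type == "ramp") s$incline <- -s$incline
      if (s$type == "turn") s$angle <- -s$angle
      s
    }))
  }
  structure(list(segments = segments, speed = speed, cadence = cadence,
                 start = start, rate = rate), class = "circuit_spec")
}

seg_length <- function(s) {
  switch(s$type,
         level = s$length,
         stairs = s$n_steps * s$run,
         ramp = s$length,
         turn = abs(s$angle) * pi / 180 * s$radius)
}

# Per-sample path profile: terrain slope dz/ds, heading rate dpsi/ds and task
# label along arc length s, with smoothstep crossfades (blend 0.2 m) so the
# resulting trajectories are C1-continuous.
circuit_profile <- function(spec, s) {
  blend <- 0.2
  slope <- numeric(length(s))
  yaw_rate <- numeric(length(s))
  label <- rep("level", length(s))
  s0 <- 0
  for (seg in spec$segments) {
    len <- seg_length(seg)
    s1 <- s0 + len
    w <- smoothstep(s, s0 - blend, s0 + blend) -
         smoothstep(s, s1 - blend, s1 + blend)
    if (seg$type == "stairs") {
      dir <- if (seg$direction == "up") 1 else -1
      slope <- slope + w * dir * seg$rise / seg$run
    } else if (seg$type == "ramp") {
      slope <- slope + w * tan(seg$incline * pi / 180)
    } else if (seg$type == "turn") {
      yaw_rate <- yaw_rate + w * (seg$angle * pi / 180) / len
    }
    label[s >= s0 & s < s1] <- switch(seg$type, stairs = "stair",
                                      ramp = "ramp", turn = "turn", "level")
    s0 <- s1
  }
  list(slope = slope, yaw_rate = yaw_rate, label = label, total = s0)
}

#' Gait-style parameters
#'
#' Joint-pattern amplitudes (radians unless noted) of the periodic walker.
#' `asymmetry` multiplies right-side limb amplitudes (1 = symmetric);
#' `tremor_amp`/`tremor_freq` add a small oscillation to the arm joints;
#' `jitter` is the log-SD of seeded per-trial amplitude variation;
#' `speed_factor` scales the circuit speed.
#'
#' @param hip_amp,knee_amp,ankle_amp,arm_swing,trunk_twist,pelvis_roll joint
#'   pattern amplitudes (rad).
#' @param sway,bob pelvis lateral sway and vertical bob amplitudes (m).
#' @param lean constant forward trunk lean (rad).
#' @param asymmetry right/left amplitude ratio (> 0).
#' @param tremor_amp tremor amplitude (rad), default 0.
#' @param tremor_freq tremor frequency (Hz).
#' @param jitter per-trial log-normal amplitude variation SD.
#' @param speed_factor multiplier on circuit speed.
#' @return object of class `gait_style`.
#' @export
gait_style <- function(hip_amp = 0.35, knee_amp = 0.55, ankle_amp = 0.25,
                       arm_swing = 0.28, trunk_twist = 0.10,
                       pelvis_roll = 0.05, sway = 0.025, bob = 0.015,
                       lean = 0.08, asymmetry = 1.0, tremor_amp = 0,
                       tremor_freq = 5, jitter = 0.05, speed_factor = 1.0) {
  stopifnot(asymmetry > 0, tremor_amp >= 0, speed_factor > 0)
  structure(as.list(environment()), class = "gait_style")
}

#' Perturb a gait style toward a parkinsonian surrogate
#'
#' Returns the style with reduced arm swing, increased left/right asymmetry,
#' reduced speed and optional low-amplitude 4-6 Hz tremor. This is a test
#' population surrogate, not a model of the disease.
#'
#' @param style a [gait_style()].
#' @param arm_swing_factor multiplier on arm-swing amplitude (default 0.6).
#' @param asymmetry right/left amplitude ratio (default 0.8).
#' @param speed_factor multiplier on speed (default 0.85).
#' @param tremor_amp,tremor_freq tremor amplitude (rad) and frequency (Hz).
#' @return modified `gait_style`.
#' @export
pd_surrogate <- function(style = gait_style(), arm_swing_factor = 0.6,
                         asymmetry = 0.8, speed_factor = 0.85,
                         tremor_amp = 0, tremor_freq = 5) {
  style$arm_swing <- style$arm_swing * arm_swing_factor
  style$asymmetry <- asymmetry
  style$speed_factor <- style$speed_factor * speed_factor
  style$tremor_amp <- tremor_amp
  style$tremor_freq <- tremor_freq
  style
}

#' Generate one synthetic gait trial
#'
#' Drives a 12-segment kinematic chain along the circuit: the pelvis root
#' follows the path (heading, terrain height, sway and bob), legs and arms
#' follow phase-locked sinusoid-plus-harmonic joint patterns with stair/ramp
#' amplitude modulation, and the trunk follows the path tangent with
#' counter-rotation. Emits the full marker set, ground-truth segment poses
#' and per-frame task labels; reproducible by seed.
#'
#' @param circuit a [circuit_spec()].
#' @param style a [gait_style()].
#' @param subject list with `height` (m) and `mass` (kg).
#' @param seed integer seed for the per-trial style jitter.
#' @param model optional precomputed [body_model()] for the subject.
#' @return object of class `gait_trial`: `markers` (n x 3 x labels),
#'   `poses` (ground truth), `labels` (task per frame), `model`, `rate`,
#'   `seed` and the generating spec/style.
#' @export
generate_trial <- function(circuit = circuit_spec(), style = gait_style(),
                           subject = list(height = 1.75, mass = 70),
                           seed = 1L, model = NULL) {
  if (is.null(model)) model <- body_model(subject$height, subject$mass)
  rate <- circuit$rate
  dt <- 1 / rate

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  jit <- function() exp(stats::rnorm(1, 0, style$jitter))
  amp <- list(hip = style$hip_amp * jit(), knee = style$knee_amp * jit(),
              ankle = style$ankle_amp * jit(), arm = style$arm_swing * jit(),
              twist = style$trunk_twist * jit(), roll = style$pelvis_roll,
              sway = style$sway * jit(), bob = style$bob * jit())
  phase0 <- stats::rnorm(1, 0, 2 * style$jitter)
  speed <- circuit$speed * style$speed_factor *
    exp(stats::rnorm(1, 0, 0.6 * style$jitter))

  leg_len <- (model$table$thigh$length_fraction +
              model$table$shank$length_fraction) * model$height
  step_len <- speed * 60 / circuit$cadence
  if (step_len > leg_len)
    stop("infeasible spec: step length ", round(step_len, 2),
         " m exceeds leg length ", round(leg_len, 2), " m")

  prof0 <- circuit_profile(circuit, 0)
  duration <- if (speed < 1e-6) 10 else prof0$total / speed
  n <- round(duration * rate) + 1
  t <- (seq_len(n) - 1) * dt
  s <- speed * t
  prof <- circuit_profile(circuit, s)

  # path integration (heading and height from C1 profiles)
  psi <- cumsum(prof$yaw_rate * speed * dt)
  z_terr <- cumsum(prof$slope * speed * dt)
  x <- cumsum(cos(psi) * speed * dt)
  y <- cumsum(sin(psi) * speed * dt)

  f_str <- circuit$cadence / 120          # stride frequency (Hz)
  phi <- 2 * pi * f_str * t + phase0
  lead <- circuit$lead_leg %||% "L"
  if (identical(lead, "R")) phi <- phi + pi
  phiL <- phi; phiR <- phi + pi

  # task weights for joint-pattern modulation
  w_up <- pmax(prof$slope, 0) / 0.5
  w_dn <- pmax(-prof$slope, 0) / 0.5
  stair_w <- smoothstep(abs(prof$slope), 0.2, 0.4)

  tremor <- if (style$tremor_amp > 0)
    style$tremor_amp * sin(2 * pi * style$tremor_freq * t) else 0

  joint <- function(phis, side_fac, arm_fac) {
    hip <- amp$hip * side_fac * sin(phis) + 0.35 * w_up + 0.10 * w_dn
    knee <- (amp$knee * side_fac + 0.45 * stair_w) *
      (0.5 - 0.5 * cos(phis - 0.35)) +
      0.25 * amp$knee * (0.5 - 0.5 * cos(2 * phis - 0.8))
    ankle <- 0.5 * amp$ankle * side_fac * sin(phis + 1.2)
    sho <- -amp$arm * arm_fac * sin(phis) + 0.05 + tremor
    elb <- 0.35 + 0.25 * amp$arm * arm_fac * (0.5 - 0.5 * cos(phis + pi)) +
      tremor
    list(hip = hip, knee = knee, ankle = ankle, sho = sho, elb = elb)
  }
  jL <- joint(phiL, 1, 1)
  jR <- joint(phiR, style$asymmetry, style$asymmetry)

  roll <- amp$roll * sin(phi)
  twist <- amp$twist * sin(phi + pi)
  lean <- style$lean + 0.4 * atan(prof$slope)
  z_root <- z_terr + 0.96 * model$geometry$hip_height + amp$bob * cos(2 * phi)
  sway_off <- amp$sway * sin(phi)
  root <- cbind(x - sway_off * sin(psi), y + sway_off * cos(psi), z_root)

  segs <- model$segments
  Lp <- segs$pelvis$length; Lt <- segs$torso$length
  w_hip <- model$geometry$hip_width; w_sho <- model$geometry$shoulder_width

  poses <- lapply(segs, function(sg)
    list(R = array(0, c(3, 3, n)), origin = matrix(0, n, 3)))
  n_mark <- sum(vapply(segs, function(sg) nrow(sg$markers), 0L))
  labels <- unlist(lapply(segs, function(sg) rownames(sg$markers)),
                   use.names = FALSE)
  markers <- array(0, c(n, 3, n_mark), dimnames = list(NULL, NULL, labels))

  put <- function(i, nm, R, origin) {
    origin <- as.vector(origin)
    poses[[nm]]$R[, , i] <<- R
    poses[[nm]]$origin[i, ] <<- origin
    markers[i, , rownames(segs[[nm]]$markers)] <<-
      R %*% t(segs[[nm]]$markers) + origin
  }

  for (i in seq_len(n)) {
    Rp <- rot_z(psi[i]) %*% rot_x(roll[i])
    put(i, "pelvis", Rp, root[i, ])
    Rt <- Rp %*% rot_z(twist[i]) %*% rot_y(-lean[i])
    torso_o <- root[i, ] + Rp %*% c(0, 0, Lp)
    put(i, "torso", Rt, torso_o)
    for (side in c("L", "R")) {
      sg <- if (side == "L") 1 else -1
      j <- if (side == "L") jL else jR
      hip_o <- root[i, ] + Rp %*% c(0, sg * w_hip / 2, 0)
      R_th <- Rp %*% rot_y(-j$hip[i])
      put(i, paste0(side, "_thigh"), R_th, hip_o)
      knee_o <- hip_o + R_th %*% c(0, 0, -segs[[paste0(side, "_thigh")]]$length)
      R_sh <- R_th %*% rot_y(j$knee[i])
      put(i, paste0(side, "_shank"), R_sh, knee_o)
      ank_o <- knee_o + R_sh %*% c(0, 0, -segs[[paste0(side, "_shank")]]$length)
      R_ft <- R_sh %*% rot_y(-j$ankle[i])
      put(i, paste0(side, "_foot"), R_ft, ank_o)
      sho_o <- torso_o + Rt %*% c(0, sg * w_sho / 2, Lt)
      R_ua <- Rt %*% rot_y(-j$sho[i])
      put(i, paste0(side, "_upper_arm"), R_ua, sho_o)
      elb_o <- sho_o + R_ua %*% c(0, 0, -segs[[paste0(side, "_upper_arm")]]$length)
      R_fa <- R_ua %*% rot_y(-j$elb[i])
      put(i, paste0(side, "_forearm"), R_fa, elb_o)
    }
  }

  structure(list(markers = markers, poses = poses, labels = prof$label,
                 model = model, rate = rate, dt = dt, subject = subject,
                 circuit = circuit, style = style, seed = as.integer(seed),
                 duration = duration),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat("<gait_trial>", dim(x$markers)[1], "frames at", x$rate, "Hz,",
      dim(x$markers)[3], "markers, subject", x$subject$height, "m /",
      x$subject$mass, "kg, start", x$circuit$start, "\n")
  invisible(x)
}

#' Default able-bodied anthropometric profiles
#'
#' Five stature/mass profiles whose mean (SD) match a typical young
#' able-bodied cohort: height 1.75 (0.11) m, mass 66.8 (12.2) kg.
#' @return list of `list(height, mass)` profiles.
#' @export
able_bodied_profiles <- function() {
  list(list(height = 1.60, mass = 50), list(height = 1.69, mass = 59),
       list(height = 1.75, mass = 67), list(height = 1.81, mass = 75),
       list(height = 1.90, mass = 83))
}

#' Parkinsonian-surrogate anthropometric profiles
#'
#' Five stature/mass profiles for the perturbed-gait surrogate cohort.
#' @return list of `list(height, mass)` profiles.
#' @export
pd_profiles <- function() {
  list(list(height = 1.72, mass = 94.8), list(height = 1.72, mass = 54.4),
       list(height = 1.72, mass = 82.6), list(height = 1.80, mass = 92.5),
       list(height = 1.72, mass = 63.5))
}

#' Generate a cohort of synthetic trials
#'
#' Cycles subjects through the anthropometric profiles, alternates the start
#' point A/B between consecutive trials and the lead leg every second trial
#' (schedule A,B,A,B... and L,L,R,R...), and derives a distinct per-trial
#' seed from the master seed.
#'
#' @param n_trials number of trials (>= 1).
#' @param profiles list of `list(height, mass)` anthropometric profiles.
#' @param circuit a [circuit_spec()].
#' @param style a [gait_style()].
#' @param seed master seed.
#' @return object of class `trial_set`: list of `gait_trial`s plus an empty
#'   partition slot (see [partition_trials()]).
#' @export
make_cohort <- function(n_trials, profiles = able_bodied_profiles(),
                        circuit = circuit_spec(), style = gait_style(),
                        seed = 1L) {
  stopifnot(n_trials >= 1)
  models <- lapply(profiles, function(p) body_model(p$height, p$mass))
  trials <- vector("list", n_trials)
  base_segments <- circuit$segments
  if (circuit$start == "B")   # store segments in canonical (A) order
    base_segments <- circuit_spec(segments = circuit$segments,
                                  speed = circuit$speed,
                                  cadence = circuit$cadence, start = "B",
                                  rate = circuit$rate)$segments
  for (i in seq_len(n_trials)) {
    k <- ((i - 1) %% length(profiles)) + 1
    ci <- circuit_spec(segments = base_segments, speed = circuit$speed,
                       cadence = circuit$cadence,
                       start = if (i %% 2 == 1) "A" else "B",
                       rate = circuit$rate)
    ci$lead_leg <- if (((i - 1) %% 4) < 2) "L" else "R"
    trials[[i]] <- generate_trial(ci, style, profiles[[k]],
                                  seed = derive_seed(seed, i),
                                  model = models[[k]])
  }
  structure(list(trials = trials, partition = NULL, seed = as.integer(seed)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat("<trial_set>", length(x$trials), "trials")
  if (!is.null(x$partition))
    cat(" (", sum(x$partition == "train"), "train /",
        sum(x$partition == "val"), "val /", sum(x$partition == "test"),
        "test )")
  cat("\n")
  invisible(x)
}
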