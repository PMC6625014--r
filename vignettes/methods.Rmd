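---
title: "Estimating segmental angular momentum from five virtual IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating segmental angular momentum from five virtual IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(momnet)
```

## The quantity being estimated

Whole-body angular momentum about the body center of mass, $H$, is tightly
regulated during healthy walking and is a direct, Newtonian measure of
balance control. Its decomposition over body segments localizes coordination
deficits — useful in asymmetric conditions where summary metrics such as
gait speed cannot distinguish the affected from the unaffected side. Each
segment $i$ contributes an orbital and a spin term,

$$
H_i \;=\; (r_i - r_{body}) \times m_i\,(v_i - v_{body}) \;+\; I_i\,\omega_i ,
$$

where $r_i, v_i$ are the segment COM position and velocity, $r_{body},
v_{body}$ the whole-body COM position and velocity (mass-weighted means over
the 12 modeled segments), $m_i$ the segment mass, $I_i$ the inertia tensor
expressed in the laboratory frame at the segment COM, and $\omega_i$ the
segment angular velocity. Superposition holds exactly: the sum of the
contributions is the whole-body momentum about the COM. The test suite
verifies this against an independent point-cloud discretization (six point
masses per segment reproducing $m$, COM and $I$) to a relative error below
$10^{-9}$, and verifies conservation of the total on a simulated
free-floating, torque-free three-body system.

Contributions are re-expressed in a moving body-aligned frame: the vertical
axis is the lab vertical, the anterior axis is the trunk's anterior axis
projected into the horizontal plane, and the mediolateral axis completes the
right-handed triad. Components about the mediolateral, anterior and vertical
axes are reported as the sagittal-, frontal- and transverse-plane momenta.
The twelve segments are grouped into five reported signals — each leg
(thigh + shank + foot), each arm (upper arm + forearm), and the trunk
(torso + pelvis) — giving $5 \times 3 = 15$ channels, normalized by subject
height $\times$ mass and smoothed with a centered 5-frame moving average.

## The sparse-sensing problem and the network

Fully instrumenting a patient is impractical; the package instead maps
signals available to five wearable inertial sensors — three-axis linear
acceleration and angular velocity at the two wrists, two ankles and the
neck, 30 channels in all — onto the 15 momentum channels. The map is a NARX
network (nonlinear autoregressive with exogenous inputs): a single hidden
layer of 30 logistic-sigmoid units and 15 linear outputs, fed by tapped
delay lines carrying the current and eight previous inputs (taps 0–8) and
the eight previous outputs (taps 1–8), a 390-dimensional regressor. Lag 0
is excluded from the output taps because the current output is the
prediction target; this also reconciles "previous eight" with "current and
eight prior" phrasings of tapped-delay conventions. Both tap sets are
configurable.

Training is batch scaled conjugate gradient (Møller's algorithm): conjugate
directions with a Levenberg–Marquardt scale $\lambda$, Hessian–vector
products approximated by finite-differencing the gradient
($\sigma = 5\times10^{-5}$, initial $\lambda = 5\times10^{-7}$, restart
every $N$ iterations where $N$ is the parameter count). The analytic
backpropagated gradient is checked against central finite differences to
$10^{-6}$ relative error in the test suite. Channels are min–max scaled to
$[-1, 1]$ with scalers fitted on the training partition only — standard
practice for sigmoid networks; the scalers are tiled across the tap blocks
of the regressor. Weights initialize uniformly in
$[\pm 1/\sqrt{\text{fan-in}}]$ from a seeded generator, so the entire
pipeline is bit-reproducible given the master seed.

Training is open-loop (series–parallel): output taps carry ground-truth
history, i.e. teacher forcing. Evaluation is reported in both modes —
open-loop, and closed-loop where the network feeds back its own
predictions. The headline accuracy surface is open-loop; in the default
experiment the closed-loop simulation is substantially worse, which is the
expected failure mode of teacher-forced autoregressive models (the network
learns to lean on the highly informative one-frame-old output and
accumulates drift when that input is replaced by its own predictions). Both
numbers appear in every report so the trade-off is visible.

Early stopping selects the weights with the best validation mean-squared
error and halts after 6 consecutive validation increases; the epoch cap
defaults to 400, chosen from the optimizer's convergence profile on the
default cohorts (validation improvement has largely tapered by then).
Partitioning is 70/15/15 by whole trial, never by frame — frames within a
trial are strongly autocorrelated, and partitioning by frame would leak
test information into training.

## Virtual inertial sensors

Sensor frames are constructed from markers: wrist sensors at the midpoint
of the radial and ulnar styloids with $z$ toward the elbow joint center
(epicondyle-marker midpoint) and $y$ toward a dorsal hand marker; ankle
sensors at the malleolus midpoint with $z$ toward the knee joint center and
$y$ lateral; the neck sensor at C7 with $z$ toward the PSIS midpoint and
$y$ posterior in the plane of C7, the PSIS midpoint and the jugular notch.
The $z$ rule is exact; the anatomical $y$ hint only seeds
$x = y_{hint} \times z$, after which $y = z \times x$, so every triad is
exactly orthonormal even when the hint is not perpendicular to $z$.

The accelerometer models specific force $f = a - g$ with
$g = (0, 0, -9.81)\,\mathrm{m/s^2}$: a sensor at rest reads
$+9.81\,\mathrm{m/s^2}$ along its up axis, matching real IMUs. The
gyroscope reads the frame angular velocity, extracted from the rotation
series via the skew-symmetric part of $\dot R R^\top$; both are rotated
into the local frame. Test-time sensor noise is zero-mean Gaussian with
$\sigma = 0.15\,\mathrm{m/s^2}$ (accelerometer) and
$\sigma = 0.005\,\mathrm{rad/s}$ (gyroscope) — noise is injected only when
testing, never during training, replicating a train-clean / test-noisy
protocol; a pipeline flag controls this. Signals are smoothed with the same
centered 5-frame moving average as the momenta, applied after noise
injection as a real device would. Bias drift, scale-factor error and sensor
misplacement are deliberately out of scope.

## The synthetic gait generator

No public motion-capture data accompany this problem, so the package
generates its own: a 12-segment kinematic chain whose pelvis follows a
locomotor circuit — by default 3 m level ground, a 4-step staircase (rise
0.15 m, run 0.30 m), a 180° turn, a 2.5 m ramp at 10°, and 3 m level — at
1.1 m/s and 110 steps/min, producing trials of roughly 10–12 s at 100 Hz.
Trials alternate start point (A/B traverses the circuit forward/reversed,
exchanging stair ascent for descent) and lead leg on an A,B,A,B / L,L,R,R
schedule. Joints follow phase-locked sinusoid-plus-harmonic patterns (hip,
knee, ankle, shoulder, elbow), with stair/ramp segments modulating hip and
knee amplitudes through smoothstep-blended task weights; heading and
terrain height are $C^1$-continuous. Five anthropometric profiles (heights
1.60–1.90 m, masses 50–83 kg, matching a typical young able-bodied cohort
mean (SD) of 1.75 (0.11) m and 66.8 (12.2) kg) cycle across trials, and a
seeded log-normal jitter (SD 0.05) varies amplitudes, phase and speed
per trial.

The generator is kinematic, not dynamic: no ground-reaction forces, no
contact model, and foot trajectories are not constrained to the floor. This
is sufficient because the momentum computation needs only kinematics plus
inertia, and it keeps every stage deterministic and desk-scale. The
generator emits exactly the marker set the body model tracks (four or more
markers rigid in every segment frame plus the named landmarks), so
least-squares pose tracking recovers the generating poses to $10^{-8}$ on
noise-free markers — a closure property the tests assert.

A perturbed-gait surrogate cohort models the direction (not the magnitude)
of parkinsonian changes: arm swing reduced to 0.6×, right/left amplitude
asymmetry 0.8, speed 0.85×, and optional 4–6 Hz tremor (off by default). Its
anthropometric profiles are five heavier/shorter subjects (1.72–1.80 m,
54.4–94.8 kg). Passing the transfer test on this cohort shows robustness to
these specific style and anthropometric shifts — it does not show clinical
validity on real patients, whose variability (tremor type, bradykinesia,
freezing) the generator does not attempt to reproduce.

## Numerical choices

* **Marker smoothing** — zero-lag 4th-order Butterworth, 6 Hz cutoff at
  100 Hz, applied forward and backward (the bidirectional pass doubles the
  effective order; the order is specified per pass, following
  motion-capture convention). The signal is extended by odd reflection
  (about ten cutoff periods) before filtering to suppress edge transients;
  DC gain is 1 to $10^{-8}$ and a 40 Hz tone is attenuated below 1%.
* **Differentiation** — central differences on interior frames, one-sided
  at the two ends; derivative-based tests evaluate interior frames only.
* **Moving average** — centered odd window with symmetric shrink at the
  boundaries (zero phase, like the Butterworth choice; no group delay).
* **Rigid fit** — orthogonal Procrustes via SVD with the determinant sign
  fixed to a proper rotation; near-collinear marker configurations (second
  singular value below $10^{-9}$ of the first) raise a degenerate-geometry
  error. With 1 mm marker jitter on a segment-scale six-marker cloud the
  rotation error stays below 0.5°.
* **Degenerate inputs** — radii of gyration are floored at $10^{-6}$ so
  inertia tensors stay positive definite; scaler ranges are floored at
  $10^{-8}$; a trunk anterior axis within 1° of vertical raises an error
  rather than returning an ill-conditioned body frame; step length
  exceeding leg length rejects a circuit as infeasible.
* **Anthropometric table** — the bundled table is a de Leva-style
  adjusted-Zatsiorsky set with the head folded into the torso and the hand
  into the forearm so the 12 segments carry the entire body mass. It is a
  documented stand-in (the exact inertia parameterization used with
  commercial modeling tools is not public) and is swappable via a YAML
  config; results depend on these ratios only through the momentum
  normalization, not on any specific published source.
* **Normalization order** — traces are normalized by height × mass and then
  smoothed; both operations are linear, so the order is immaterial, and
  normalize-then-smooth is what the implementation fixes.

## Problem sizes and reproducibility

The default experiment (`experiment_config()`) uses 70 able-bodied-style
trials (50 train / 10 validation / 10 test after the 70/15/15 split) and a
20-trial surrogate cohort, ~1000–1200 frames per trial; training the
390-input network takes a few minutes of batch SCG on one core. These sizes
were chosen as the smallest cohorts at which the train/validation/test
machinery operates as designed with whole-trial partitions; the unit tests
run the same code paths on much smaller configurations. Every random choice
(trial jitter, partition, weight initialization, sensor noise) derives from
one master seed, and re-running the experiment with the same seed
reproduces the report bit for bit — the acceptance script recomputes its
numbers from scratch on each invocation.

## Known limitations

* The generator's joint patterns have gait-like bandwidth and task
  structure but no claim of physiological fidelity; errors measured on it
  bound what the pipeline can do on clean, well-labeled data, not on real
  mocap with soft-tissue artifact, marker occlusion or mislabeling.
* Closed-loop (free-running) prediction degrades relative to open-loop;
  applications needing long-horizon simulation rather than one-step-ahead
  estimation would need closed-loop (parallel-mode) training, which is out
  of scope.
* The C3D binary format is not read; marker data enter via TRC or the
  in-memory array interface.
* No hypothesis testing between cohorts, no integrated-momentum metrics,
  and no physical-sensor effects beyond additive Gaussian noise.
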