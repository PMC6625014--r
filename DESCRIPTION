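Package: momnet
Title: Sparse-Sensor Estimation of Segmental Angular Momentum During Gait
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-segment contributions to whole-body angular momentum
    from full-body gait kinematics, synthesizes noisy virtual inertial
    measurement unit (IMU) signals at five body locations (wrists, ankles,
    neck), and trains a dynamic nonlinear autoregressive network with
    exogenous inputs (NARX) that maps the sparse 30-channel IMU stream to the
    15-channel segmental momentum stream. Includes a kinematic articulated
    gait generator for a non-steady-state locomotor circuit (level walking,
    stairs, ramp, turns) so the full pipeline can be trained and evaluated
    without motion-capture data, plus evaluation utilities (pooled
    correlation, peak-normalized RMS error) and an end-to-end experiment
    driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
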