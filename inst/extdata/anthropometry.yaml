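# Body-segment inertial parameters for the 12-segment model.
#
# Values are in the style of published adjusted-Zatsiorsky tables (de Leva
# 1996), with two folds so that exactly 12 segments carry the whole body
# mass: the head+neck is folded into the torso, and the hand into the
# forearm. The table is a documented stand-in, overridable by the user;
# results depend on these ratios, not on any specific published source.
#
# Per segment:
#   mass_fraction   : fraction of total body mass (dimensionless)
#   length_fraction : segment length as fraction of stature (dimensionless)
#   com_fraction    : COM location along the long axis, fraction of segment
#                     length from the proximal end
#   gyration        : principal radii of gyration about [x, y, z] local axes,
#                     as fractions of segment length (z = longitudinal)
segments:
  pelvis:
    mass_fraction: 0.1117
    length_fraction: 0.090
    com_fraction: 0.390
    gyration: [0.615, 0.551, 0.587]
  torso:
    mass_fraction: 0.3923       # upper+mid trunk with head+neck folded in
    length_fraction: 0.198
    com_fraction: 0.560
    gyration: [0.372, 0.347, 0.191]
  upper_arm:
    mass_fraction: 0.0271
    length_fraction: 0.186
    com_fraction: 0.577
    gyration: [0.285, 0.269, 0.158]
  forearm:
    mass_fraction: 0.0223       # forearm with hand folded in
    length_fraction: 0.146
    com_fraction: 0.620
    gyration: [0.276, 0.265, 0.121]
  thigh:
    mass_fraction: 0.1416
    length_fraction: 0.245
    com_fraction: 0.410
    gyration: [0.329, 0.329, 0.149]
  shank:
    mass_fraction: 0.0433
    length_fraction: 0.246
    com_fraction: 0.446
    gyration: [0.255, 0.249, 0.103]
  foot:
    mass_fraction: 0.0137
    length_fraction: 0.152
    com_fraction: 0.442
    gyration: [0.257, 0.245, 0.124]
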