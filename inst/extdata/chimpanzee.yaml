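# Chimpanzee glenohumeral model parameters.
#
# Printed model inputs as in the human file. PCSAs: whole-muscle chimpanzee
# infraspinatus (24.42 cm^2) and subscapularis (46.07 cm^2) were partitioned
# into elements using the human element shares (infra upper/lower
# 0.4537/0.5463; subscap upper/middle/lower 0.24292/0.31931/0.43777), giving
# the printed element values 11.08/13.34 and 11.19/14.71/20.17.
# Standard deviations are identical to the human file for every input.
# The stability offset of 13.13% encodes the deeper chimpanzee glenoid.
# Fixture values are synthetic-geometry assumptions scaled to chimpanzee
# segment dimensions.
species: chimpanzee
body_mass: 45.0     # kg
stature: 1.32       # m

segment_lengths:    # m, fixture-derived (forearm longer than arm in apes)
  arm: 0.277
  forearm: 0.284
  hand: 0.119
segment_mass_fractions:
  arm: 0.045
  forearm: 0.030
  hand: 0.010

bone_lengths:
  scapula: 0.130
  humerus: 0.277

fixture:
  scapula_top_fraction: 0.29
  glenoid_centroid_offset: 0.021
  humeral_head_radius: 0.023
  shaft_radius: 0.0075
  acromion_offset: [-0.016, 0.029, 0.008]

glenoid:
  inclination_mean_cm: 104.78
  inclination_sd_cm: 0.3

stability:
  directions: [superior, anterosuperior, anterior, anteroinferior,
               inferior, posteroinferior, posterior, posterosuperior]
  baseline: [0.45, 0.50, 0.55, 0.60, 0.65, 0.60, 0.55, 0.50]
  offset_pct: 13.13
  sd_pct: 4.0
  offset_mode: multiplicative

attachment_distributions:
  infraspinatus_origin:
    bone: scapula
    mean: [-0.200, 0.300, 0.587]
    sd:   [0.010, 0.035, 0.035]
  subscapularis_origin:
    bone: scapula
    mean: [-0.0615, 0.162, 0.643]
    sd:   [0.010, 0.035, 0.035]
  supraspinatus_origin:
    bone: scapula
    mean: [-0.051, 0.125, 0.460]
    sd:   [0.010, 0.035, 0.035]
  deltoid_insertion:
    bone: humerus
    mean: [0.0315, 0.0415, 0.346]
    sd:   [0.035, 0.010, 0.035]

muscle_elements:
  - name: deltoid_anterior
    absolute_pcsa: 12.10
    printed_relative_pcsa: 0.269
    origin:    {bone: scapula, fixed: [0.190, -0.250, 0.010]}
    insertion: {bone: humerus, parent: deltoid_middle, offsets: [0.25, -0.05, -0.02]}
    wrap: shaft_cylinder
  - name: deltoid_middle
    absolute_pcsa: 28.95
    printed_relative_pcsa: 0.643
    origin:    {bone: scapula, fixed: [0.080, -0.350, 0.000]}
    insertion: {bone: humerus, group: deltoid_insertion}
    wrap: shaft_cylinder
  - name: deltoid_posterior
    absolute_pcsa: 11.06
    printed_relative_pcsa: 0.246
    origin:    {bone: scapula, fixed: [-0.030, 0.120, 0.080]}
    insertion: {bone: humerus, parent: deltoid_middle, offsets: [-0.25, 0.05, 0.02]}
    wrap: shaft_cylinder
  - name: infraspinatus_upper
    absolute_pcsa: 11.08
    printed_relative_pcsa: 0.246
    origin:    {bone: scapula, group: infraspinatus_origin}
    insertion: {bone: humerus, fixed: [-0.045, 0.075, 0.085]}
    wrap: humeral_head
  - name: infraspinatus_lower
    absolute_pcsa: 13.34
    printed_relative_pcsa: 0.296
    origin:    {bone: scapula, parent: infraspinatus_upper, offsets: [0.100000, 0.100000, 0.158433]}
    insertion: {bone: humerus, fixed: [-0.055, 0.065, 0.100]}
    wrap: humeral_head
  - name: subscapularis_upper
    absolute_pcsa: 11.19
    printed_relative_pcsa: 0.249
    origin:    {bone: scapula, group: subscapularis_origin}
    insertion: {bone: humerus, fixed: [0.060, 0.050, 0.075]}
    wrap: humeral_head
  - name: subscapularis_middle
    absolute_pcsa: 14.71
    printed_relative_pcsa: 0.327
    origin:    {bone: scapula, parent: subscapularis_upper, offsets: [0.073171, 0.111111, 0.088647]}
    insertion: {bone: humerus, fixed: [0.065, 0.045, 0.090]}
    wrap: humeral_head
  - name: subscapularis_lower
    absolute_pcsa: 20.17
    printed_relative_pcsa: 0.448
    origin:    {bone: scapula, parent: subscapularis_upper, offsets: [0.138211, 0.234568, 0.181959]}
    insertion: {bone: humerus, fixed: [0.060, 0.040, 0.110]}
    wrap: humeral_head
  - name: supraspinatus
    absolute_pcsa: 19.92
    printed_relative_pcsa: 0.443
    origin:    {bone: scapula, group: supraspinatus_origin}
    insertion: {bone: humerus, fixed: [0.000, 0.085, 0.075]}
    wrap: humeral_head
  - name: teres_minor
    absolute_pcsa: 5.48
    printed_relative_pcsa: 0.122
    origin:    {bone: scapula, fixed: [-0.205, 0.150, 0.800]}
    insertion: {bone: humerus, fixed: [-0.065, 0.050, 0.120]}
    wrap: humeral_head
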