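# Human glenohumeral model parameters.
#
# Printed model inputs: body mass/stature; the four perturbed attachment
# distributions (means as fractions of longitudinal bone length, axis order
# anterior-posterior, medial-lateral, superior-inferior); glenoid inclination
# (global mediolateral coordinate of the superior glenoid landmark, cm); the
# stability-ratio offset/SD (%); and muscle PCSAs (cm^2, already doubled to
# represent young healthy adults).
#
# Everything under `fixture:` plus fixed attachment fractions, coupling
# offsets, baseline directional stability ratios, and segment mass fractions
# is an assumption of this package's synthetic geometry (documented in the
# methods vignette), not a printed value.
species: human
body_mass: 72.0     # kg
stature: 1.80       # m

segment_lengths:    # m, fixture-derived (Winter-style fractions of stature)
  arm: 0.335
  forearm: 0.263
  hand: 0.194
segment_mass_fractions:   # fraction of body mass per segment
  arm: 0.028
  forearm: 0.016
  hand: 0.006

bone_lengths:       # longitudinal lengths, m
  scapula: 0.155
  humerus: 0.335

fixture:
  scapula_top_fraction: 0.29     # superior scapular reference above glenoid centroid, fraction of scapula length
  glenoid_centroid_offset: 0.025 # medial offset of glenoid centroid from GH centre, m
  humeral_head_radius: 0.026     # wrap sphere, m
  shaft_radius: 0.011            # deltoid wrap cylinder, m
  acromion_offset: [-0.020, 0.035, 0.010]  # acromion marker relative to GH, m

glenoid:
  inclination_mean_cm: 115.12
  inclination_sd_cm: 0.3

stability:
  directions: [superior, anterosuperior, anterior, anteroinferior,
               inferior, posteroinferior, posterior, posterosuperior]
  # Assumed anisotropic baseline (superior / anterosuperior weakest);
  # the deterministic model's own values are unpublished.
  baseline: [0.45, 0.50, 0.55, 0.60, 0.65, 0.60, 0.55, 0.50]
  offset_pct: 0.0
  sd_pct: 4.0
  offset_mode: multiplicative

# Perturbed attachment distributions, fractions of bone length.
# Axis order: [anterior-posterior, medial-lateral, superior-inferior].
attachment_distributions:
  infraspinatus_origin:
    bone: scapula
    mean: [-0.106, 0.240, 0.607]
    sd:   [0.010, 0.035, 0.035]
  subscapularis_origin:
    bone: scapula
    mean: [-0.030, 0.307, 0.523]
    sd:   [0.010, 0.035, 0.035]
  supraspinatus_origin:
    bone: scapula
    mean: [-0.050, 0.315, 0.360]
    sd:   [0.010, 0.035, 0.035]
  deltoid_insertion:
    bone: humerus
    mean: [-0.004, 0.064, 0.369]
    sd:   [0.035, 0.010, 0.035]

# Ten muscle elements. Attachments are either tied to a perturbed
# distribution (`group`), fixed fractions (`fixed`), or coupled to a parent
# element's attachment by per-axis fractional offsets (`parent`/`offsets`,
# child = parent * (1 + offset)).
muscle_elements:
  - name: deltoid_anterior
    absolute_pcsa: 8.84
    printed_relative_pcsa: 0.123
    origin:    {bone: scapula, fixed: [0.120, -0.250, 0.010]}
    insertion: {bone: humerus, parent: deltoid_middle, offsets: [0.25, -0.05, -0.02]}
    wrap: shaft_cylinder
  - name: deltoid_middle
    absolute_pcsa: 7.42
    printed_relative_pcsa: 0.103
    origin:    {bone: scapula, fixed: [0.010, -0.350, 0.000]}
    insertion: {bone: humerus, group: deltoid_insertion}
    wrap: shaft_cylinder
  - name: deltoid_posterior
    absolute_pcsa: 4.29
    printed_relative_pcsa: 0.060
    origin:    {bone: scapula, fixed: [-0.100, 0.120, 0.080]}
    insertion: {bone: humerus, parent: deltoid_middle, offsets: [-0.25, 0.05, 0.02]}
    wrap: shaft_cylinder
  - name: infraspinatus_upper
    absolute_pcsa: 6.37
    printed_relative_pcsa: 0.088
    origin:    {bone: scapula, group: infraspinatus_origin}
    insertion: {bone: humerus, fixed: [-0.045, 0.075, 0.085]}
    wrap: humeral_head
  - name: infraspinatus_lower
    absolute_pcsa: 7.67
    printed_relative_pcsa: 0.107
    origin:    {bone: scapula, parent: infraspinatus_upper, offsets: [0.132075, 0.125000, 0.153213]}
    insertion: {bone: humerus, fixed: [-0.055, 0.065, 0.100]}
    wrap: humeral_head
  - name: subscapularis_upper
    absolute_pcsa: 2.83
    printed_relative_pcsa: 0.039
    origin:    {bone: scapula, group: subscapularis_origin}
    insertion: {bone: humerus, fixed: [0.060, 0.050, 0.075]}
    wrap: humeral_head
  - name: subscapularis_middle
    absolute_pcsa: 3.72
    printed_relative_pcsa: 0.052
    origin:    {bone: scapula, parent: subscapularis_upper, offsets: [0.133333, 0.074919, 0.166348]}
    insertion: {bone: humerus, fixed: [0.065, 0.045, 0.090]}
    wrap: humeral_head
  - name: subscapularis_lower
    absolute_pcsa: 5.10
    printed_relative_pcsa: 0.071
    origin:    {bone: scapula, parent: subscapularis_upper, offsets: [0.266667, 0.140065, 0.338432]}
    insertion: {bone: humerus, fixed: [0.060, 0.040, 0.110]}
    wrap: humeral_head
  - name: supraspinatus
    absolute_pcsa: 3.15
    printed_relative_pcsa: 0.044
    origin:    {bone: scapula, group: supraspinatus_origin}
    insertion: {bone: humerus, fixed: [0.000, 0.085, 0.075]}
    wrap: humeral_head
  - name: teres_minor
    absolute_pcsa: 2.81
    printed_relative_pcsa: 0.039
    origin:    {bone: scapula, fixed: [-0.110, 0.170, 0.780]}
    insertion: {bone: humerus, fixed: [-0.065, 0.050, 0.120]}
    wrap: humeral_head
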