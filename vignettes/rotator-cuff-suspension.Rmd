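---
title: "Probabilistic rotator cuff force prediction during bimanual arm suspension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic rotator cuff force prediction during bimanual arm suspension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuffmc)
```

## The scientific problem

Humans and chimpanzees share a broadly similar shoulder architecture but use
it very differently: the chimpanzee glenohumeral joint is a weight-bearing
locomotor joint, while the human joint is specialized for non-weight-bearing,
below-shoulder-height manipulation. `cuffmc` implements a comparative
probabilistic model of rotator cuff function during the support phase of
horizontal bimanual arm suspension (hand-over-hand overhead locomotion), the
task most often invoked when linking shoulder morphology to arborealism. The
question the pipeline addresses is whether realistic variation in a small set
of evolutionarily salient morphological features — rotator cuff origins,
deltoid insertion, glenoid inclination, and intrinsic glenoid stability —
can move one species' predicted cuff muscle forces toward the other's.

## Model structure

The pipeline has three deterministic stages wrapped by a probabilistic
engine:

1. **External dynamics** (`hand_force()`, `gh_load()`). Three static support
   instances are analyzed: early and late support (double support, hand
   force equal to half body weight) and mid support (single support, full
   body weight). Static inverse dynamics over the arm free body yields the
   net moment about the glenohumeral (GH) centre and the reaction-force
   demand the glenoid must carry.

2. **Musculoskeletal geometry** (`build_model_geometry()`). Ten muscle
   elements (three deltoid, two infraspinatus, three subscapularis,
   supraspinatus, teres minor) are modeled as vector strings from origin to
   insertion, wrapped around a humeral-head sphere (cuff) or a proximal
   shaft cylinder (deltoid) using taut-string tangent-and-arc solutions.
   Attachments are expressed as fractions of longitudinal bone length in
   the axis order anterior-posterior, medial-lateral, superior-inferior.
   Lower/middle elements of the multi-element muscles are coded as
   percentage offsets from their upper element, so each muscle perturbs as
   a unit. Moment arms are `r x u` at the effective application point (the
   origin-side tangent point for humerus-fixed wraps), which makes them
   satisfy the tendon-excursion identity `dL/dtheta = -m . axis`; the test
   suite verifies this to better than 1 mm.

3. **Force prediction** (`solve_muscle_forces()`). Element forces minimize
   the stress-based cost `sum((f_i/fmax_i)^p)` (p = 3 by default, p = 2
   selectable) subject to (i) moment equilibrium about all three GH axes,
   (ii) bounds `0 <= f_i <= PCSA_i * sigma_max`, and (iii) the glenoid
   stability constraint: the dislocating shear component of the joint
   reaction may not exceed a direction-specific multiple of the concurrent
   compression. Stability is anisotropic: eight rim directions at 45-degree
   spacing carry individual shear-to-compression ratios, linearly
   interpolated at the actual shear azimuth.

The probabilistic engine perturbs fourteen inputs — four attachment groups
in three directions each, the glenoid inclination landmark, and the
stability-ratio set varied as a unit — with independent Gaussian draws
(covariance between features is assumed negligible and is not modeled),
runs the full model per draw, and reports each cuff element's force as a
percent of its maximum capacity through a cumulative distribution function
at the eleven probability levels 0.01, 0.1, ..., 0.9, 0.99. The default
design is 7 outputs x 3 instances x 2 species = 42 Monte Carlo analyses at
2500 iterations each.

## Key parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| body mass / stature | 72 kg, 1.80 m (human); 45 kg, 1.32 m (chimpanzee) | kg, m | representative adult males |
| hand force | 0.5 x or 1 x body weight | N | double vs single support |
| attachment SDs | 0.010 (AP cuff origins, ML deltoid), 0.035 elsewhere | fraction of bone length | identical between species by design, so no input has an artificially larger effect in one model |
| glenoid inclination SD | 0.3 | cm | calibrated so +/-3 SD spans about 20 degrees of inclination; the centroid-to-superior-landmark arm is `3*SD/tan(10 deg)` = 5.104 cm |
| stability offset | 0 (human), 13.13 (chimpanzee) | % | the chimpanzee glenoid is ~13.13% deeper; each directional ratio is scaled by 1.1313 (an additive interpretation is config-selectable) |
| stability SD | 4.0 | % of baseline | all eight directions perturbed together |
| `sigma_max` | 88 | N/cm^2 | specific tension; unpublished for the original models. Normalized outputs depend on it only through the force bounds, so it is exposed prominently in `study_config()` |
| objective exponent `p` | 3 | — | "stress-based" cost; 2 selectable |

The baseline directional stability-ratio profile (0.45–0.65, superior and
anterosuperior weakest) is an assumption: the deterministic models' own
values were never printed. It matches the range of published bench
measurements of glenohumeral stability ratios and preserves the documented
anisotropy (superior shear least tolerated).

## What the synthetic fixtures emulate — and what they do not

The original kinematics, bone meshes, and wrap-object placements live in
prior publications and unpublished data, so `cuffmc` generates synthetic
fixtures with the documented *structure*: three static postures with the
arm elevated above 100 degrees and the elbow near-extended, the mid-support
hand directly above the GH joint; chimpanzee postures derived from the human
kinematics by translating joint centres along unchanged segment directions
to chimpanzee segment lengths; and parametric bone templates (attachment
regions plus a humeral-head sphere and shaft cylinder) scaled to each
species.

Two fixture choices deserve emphasis. First, the postural lean angles
(+3, 0, -1.5 degrees of whole-arm lean for early/mid/late support) are
chosen so the net GH moment demands stay within what the modeled
deltoid-plus-cuff muscle set can balance; the original models recruit the
full shoulder muscle complement, which is outside this package's scope.
Second, with the printed attachment variances, a fraction of Monte
Carlo draws (typically 2–7%, up to ~15–20% for chimpanzee late support,
driven mainly by the large anterior-posterior variance of the deltoid
insertion) produce
states in which no force distribution satisfies equilibrium, bounds and
stability simultaneously. These iterations are *recorded and excluded* from
the CDFs, with counts in the run manifest — they are never silently imputed
or relaxed, because either would bias the distributions.

Consequently, passing tests demonstrate the internal correctness of the
pipeline (statics, geometry, optimization, uncertainty propagation) and the
fidelity of every printed parameter, but the absolute force distributions
are properties of this synthetic geometry, not reproductions of the
original study's headline numbers.

## Numerical choices

* **Solver.** The constrained optimization is a projected augmented
  Lagrangian: variables scaled to the unit box, L-BFGS-B inner iterations
  with analytic gradients, linear equality rows normalized, a
  feasibility-first warm start, and multiplier/penalty updates until the
  equilibrium residual is below 1e-6 N m and the stability violation below
  1e-6 N (the feasibility tolerances reported in every solution). The
  starting point is the zero vector and all tolerances are fixed, so
  solutions are deterministic. Non-convergence is reported as an infeasible
  flag with diagnostics. The test suite pins the solver against dense
  grid-search oracles on toy problems with and without binding stability
  constraints (agreement to 1e-3 N).
* **Shear smoothing.** The stability margin contains `|shear|`; the solver
  uses `sqrt(|s|^2 + eps^2)` with `eps` = 1e-8 N, a conservative smoothing
  (the smoothed margin is a lower bound). Feasibility is always judged on
  the exact margin.
* **Wrap side selection.** The taut string takes the side of the obstacle
  nearer the straight segment; the symmetric through-centre case is broken
  by a hint direction. Wrapping yields analytic tangent-plus-arc paths
  (great-circle on spheres, unrolled geodesic on cylinders).
* **Quantiles.** All CDF levels and percentile summaries use the type-7
  (linear interpolation) quantile rule, stated here for bit-exactness.
* **Sensitivity factors.** The absolute sensitivity of an output
  distribution to an input mean is estimated by central finite differences
  (step 0.1 SD) with common random numbers: the identical standard-normal
  draw matrix is reused with the shifted mean, so a null input has exactly
  zero estimated sensitivity. The factor at probability level p is
  `|dp/dmu| * sigma / p` (the nondimensional mean-perturbation form);
  sigma-only scaling is selectable. Factors are averaged across the eleven
  levels and then across the three support instances. On a linear Gaussian
  toy the estimator matches the closed form `dnorm(qnorm(p))/p` to better
  than 1% at 1e5 iterations.
* **Seeding.** Per-analysis seeds derive deterministically from the base
  seed, species and instance; identical configurations give bit-identical
  suites, manifests and CSV exports.

## Problem sizes

The full study design (2500 iterations per analysis) is the package
default. The shipped test suite and the acceptance script exercise the
identical pipeline at reduced size — 160 and 250 iterations per analysis
respectively, with sensitivity factors demonstrated on analytic toys —
sizes chosen to keep a complete 42-analysis run in the tens of seconds
while staying comfortably above the 100-feasible-sample floor that CDF
construction enforces.

## A short run

```{r example, eval = FALSE}
cfg <- study_config(n_iterations = 250, seed = 1,
                    sensitivity = list(enabled = FALSE))
suite <- run_analysis_suite(cfg)
suite$manifest$n_analyses      # 42
overlap_table(suite)[, c("output", "instance", "functional_overlap")]
render_reports(suite, "cuffmc_results")
```

## Known limitations

* Muscles are strings with point attachments: no architecture (pennation,
  fibre length), no broad attachment footprints, no passive tissue.
* The muscle set is the deltoid and rotator cuff only; other shoulder
  muscles participate in neither equilibrium nor stability, which limits
  the admissible external moments and contributes the infeasible-draw
  fraction discussed above.
* Hand forces are conservative static bounds; dynamic substrate forces in
  real brachiation exceed body weight.
* One wrap obstacle per muscle path; no multi-obstacle chains.
* Baseline stability ratios, wrap radii, fixed attachment fractions, and
  segment mass fractions are documented assumptions, not measured values.
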