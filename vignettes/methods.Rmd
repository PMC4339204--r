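---
title: "Gestational age from 3D cranial ultrasound: model, phantoms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gestational age from 3D cranial ultrasound: model, phantoms and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cranioage)
```

# The problem

Between 18 and 34 gestational weeks (GW) the fetal brain changes rapidly:
the skull grows, the cortex folds, and the sonographic appearance of sulci,
fissures and ventricles evolves on a tight developmental timetable.
`cranioage` implements a learning-based estimator of gestational age from a
single 3D ultrasound volume of the fetal head. It has three stages:

1. **Cranial parametrization** — a closed deformable surface is fitted to
   the interior skull boundary, giving an anatomically aligned coordinate
   frame without any voxel-level registration.
2. **Feature extraction** — appearance, local-size and biometric features
   are evaluated *relative to* that surface, so the same descriptor samples
   corresponding anatomy in heads of different sizes.
3. **Age regression** — a regression forest with variance-reduction
   splitting maps feature vectors to age; each leaf stores a Gaussian
   (mean, variance) over the training ages that reached it, and prediction
   averages only low-variance leaves.

Because the clinical cohorts such a model is normally trained on cannot be
redistributed, the package ships a first-class synthetic phantom generator
with exact ground truth (inner-skull surface and age). Everything the test
suite and the acceptance script report is computed on phantoms.

# The surface model

The skull surface is the bilinear interpolant of a quad control polyhedron
(a cube refined to 96 faces / 98 control vertices, `NX = 98`) refined twice
more with Catmull–Clark rules at evaluation time. Two properties are the
whole point of this construction:

* **Linearity**: every surface point is `p = t(X) %*% b(u)` where the
  basis weights `b(u)` depend only on the topology and the surface
  coordinate `u = (face, s, t)`. Catmull–Clark weights are convex, so
  `b(u) >= 0` and `sum(b(u)) = 1` — evaluation commutes with affine maps of
  the control vertices, and the continuous fitting step can solve exact
  linear subproblems.
* **Closedness/smoothness**: the refined mesh is a closed genus-0 surface;
  normals come from the bilinear patch tangents, oriented outward by the
  sign of the mesh volume.

This realization does not reproduce any particular published spherical
B-spline construction; it preserves exactly the properties the pipeline
uses (smooth closed surface, linear in the control vertices, convex
weights). Faces carry one of four coarse anatomical annotations — left and
right hemisphere, frontal cortex, and the falx ring around the midplane —
which propagate to every evaluated point; the falx points define the
midsagittal plane used by feature geometry.

Interactive alignment is replaced by a programmatic 9-DoF similarity
initialization (3 translations, 3 rotations, 3 anisotropic scales),
`initialize_surface()`.

# Edge detection

Boundary candidates come from feature asymmetry (FA): isotropic log-Gabor
filters give an even response and, through the Riesz transform, a
three-component odd response; FA is the positive part of
`(|odd| - |even| - T) / amplitude`, averaged over scales. FA is bounded in
[0, 1] and, because the noise floor `T` and the denominator guard are both
proportional to the mean amplitude, exactly contrast-invariant.

Numerical choices (all exposed as arguments):

* centre wavelengths {4, 8} mm — matched to the ~2 mm phantom skull shell
  at 0.6 mm spacing; coarser banks localize the thin shell with a visible
  inward bias;
* bandwidth ratio sigma/f = 0.55; noise floor 0.05 of the mean amplitude;
* non-maximum suppression along the local gradient orientation with
  parabolic sub-voxel refinement, clamped to half a voxel;
* candidate normals taken from the smoothed image gradient, so an
  interior-skull candidate (dark brain to bright bone) points outward.

Preprocessing for clinical-style input resamples to 0.6 mm isotropic and
applies a difference-of-Gaussians bandpass at sigma = 4 mm. On phantoms the
bandpass is optional: FA is contrast-invariant and the phantom has no
low-frequency artefacts.

# Surface fitting

With candidates `c_q` and normals `phi_q`, the fit minimizes

```
E(q, U, X) = sum_i ||c_qi - M(u_i, X)||^2 + l1 ||phi_qi - Mphi(u_i, X)||^2
           + l2 sum_{(i,j) in N} ||c_qi - c_qj||^2
           + l3 sum_i ||x_i - x_i0||^2
           + l4 sum_{(i,j) in T} ||x_i - x_j||^2
```

over the discrete correspondence vector `q`, the surface coordinates `U`
and the control vertices `X`. All energies are mm². Defaults
`l1 = 1, l2 = 0.1, l3 = 0.01, l4 = 0.1` were fixed once on phantoms.

**Discrete step.** Each surface point sees its 10 nearest candidates
within 15 mm of the initialization whose orientation agrees with the
outward surface normal (the orientation gate is what keeps the fit off the
outer skull edge, which is the nearer edge when the initialization is
inflated). Min-sum belief propagation on a BFS spanning tree of the
neighbour graph seeds iterated conditional modes on the full graph, so the
result is never worse than the independent per-point minimizer; when the
joint space has at most 20 000 assignments the minimizer is found by
exhaustive enumeration instead. Ties break to the lowest candidate index.
Points with no admissible candidate are dropped from the unary term — this
is the occlusion tolerance.

**Continuous step.** With `q` fixed the energy is a sum of squares. The
implementation uses damped block-coordinate descent rather than a joint
Levenberg–Marquardt solve: the X-step solves the exact normal equations of
the position/anchor/regularization terms (a linear system, by the
linearity of the surface in X) followed by a backtracking line search on
the full energy including the nonlinear orientation term; the U-step
improves each coordinate by a monotone local parameter search with
re-projection jumps to a coarse global coordinate grid, which is how face
transitions are handled. Every accepted move decreases the energy, so the
alternation trace is non-increasing at each half-step by construction —
the property the test suite asserts on every fit. Convergence: relative
energy decrease below 1e-4, at most 10 alternations.

A fitted mesh is audited for self-intersection with a star-shape check
(every face normal makes a positive inner product with the centroid-to-face
direction); for the quasi-ellipsoidal cranial geometry star-shapedness
implies a simple closed surface.

# Features

Feature geometry is confined to the visible (distal) hemisphere: `NPh =
200` points evenly subsampled from the side's annotated points, with the
midsagittal plane fitted to the falx-annotated points. For a point `p`
with projection `p'` on the midplane, `||p - p'||` is the local size scale.

* **Appearance** (`haar3d`, `unary`, `binary_context`): a cuboidal VOI of
  side `ls * ||p - p'||`, `ls ~ U(0, 0.5)`, sampled on a fixed 7×7×7
  trilinear grid. Sulcal placement affixes the VOI to the surface along
  the point normal; intracranial placement displaces it towards the
  midplane by `r * ||p - p'||`, `r ~ U(0, 1)`. `unary` is the sum of
  samples; `haar3d` subtracts one half-cuboid from the adjacent half
  (six templates: three split axes × two polarities; the centre sample
  plane is excluded so the halves are equal); `binary_context` differences
  unary scores at two points. VOIs leaving the volume score zero with a
  flag. Because VOI size scales with `||p - p'||`, noiseless scores are
  invariant to global head scale (tested at 2%).
* **Local size** (`size_euclid`, `size_ortho`): distance from `p` to its
  rank-j nearest neighbour among the hemisphere points (k = 9), either
  Euclidean or a signed per-axis component. With `NPh = 200` points a
  dense distance matrix is exact and cheap, so no spatial index is used.
* **Biometric** (`inner_hc`): the perimeter of the surface cut by the
  transthalamic (TT) plane, computed as the closed polyline of
  plane–triangle intersections of the refined mesh. The plane is defined
  by the *current* positions of the three mesh vertices nearest to three
  reference points, so it deforms with the surface; contour closure is
  audited (every crossed mesh edge must be shared by two crossed
  triangles), and vertices exactly on the plane are epsilon-perturbed.
  On phantoms the three reference points are placed analytically at 10% of
  the vertical extent above the equator, standing in for a manual
  three-point selection. Perimeter error on spheres/ellipsoids at the
  default tessellation is ~0.5%, and homogeneity under scaling is exact.

Whether unary scores are sums or means, and whether binary context pairs
points within or across regions, are not discriminating choices; the
implementation uses sums and unrestricted point pairs, fixed here.

# The forest

Split quality is the information gain of a univariate Gaussian age model,
`Ig = log var(parent) - sum_i w_i log var(child_i)` with population
variances, natural log, and a variance floor of 1e-6 GW² for degenerate
children. At each node `m` descriptors are drawn (kind uniform over the
enabled banks, parameters from their distributions above) and thresholds
are scanned over the ten inter-decile midpoints of each descriptor's
scores. Stopping: depth limit, fewer than `2 * min_samples = 10` examples,
or gain below 1e-3. Trees are grown on bags of fraction 0.67 drawn with
replacement. Reference hyperparameters are T = 20 trees, depth 15, m = 200;
the shipped study configuration is a reduced T = 8, depth 12, m = 50.

Prediction routes the example to one leaf per tree and averages the leaf
means with variance below `sigma_max^2 = 1.0 GW²`; when no leaf passes the
filter the mean over all reached leaves is used and flagged — the filter
would otherwise return nothing, and a flagged weak estimate is more useful
than an error. Forests are per-hemisphere and refuse mixed or mismatched
hemispheres.

Diagnostics: per-level feature-selection profiles (frequencies over split
nodes at each level, summing to one), per-example traversal path lengths,
maturation heat maps (VOI sample footprints of appearance split nodes at a
level, accumulated in a reference frame and normalized by the number of
split nodes at that level), quadratic error-margin bounds (residuals in
days split by sign, quadratic least squares per group, margin = absolute
difference of the two fits over the age grid), and longitudinal interval
consistency.

# The phantom generator

The generator defines the study conditions; its defaults are fixed and are
not tuned against test outcomes.

* **Growth law**: equatorial head circumference `HC = 11 * age - 45` mm,
  a linear law passing through ~175 mm at 20 GW and ~330 mm at 34 GW,
  consistent in magnitude with clinical growth charts over this range.
  Semi-axis ratios a : b : c = 1 : 1.30 : 1.05 (lateral,
  antero-posterior, vertical); the Ramanujan perimeter is homogeneous, so
  the inversion HC to semi-axes is exact.
* **Skull shell**: bright shell of thickness `1.5 + 0.12 (age - 18)` mm
  (progressive skull thickening) outside the inner-skull ellipsoid;
  interior tissue 0.25, background 0.08, shell 1.0 (arbitrary units).
* **Ridges** ("sulci"): dark sheets anchored to the interior surface of
  the visible hemisphere, count `floor(2 + 0.75 (age - 18))`, radial depth
  `2 + 0.4 (age - 18)` mm, fanned in angle about the lateral axis. Their
  number and depth are the age signal available to appearance features.
* **Falx**: a bright 1.2 mm midline sheet defining the midsagittal plane.
* **Occlusion**: the proximal hemisphere is attenuated by
  `exp(-0.025 mm^-1 * depth)`, emulating reverberation shadowing.
* **Speckle**: multiplicative Rayleigh-like noise, `I * ((1 - s) + s * E)`
  with `E` a mean-one Rayleigh variate and `s = 0.4` by default.
* **Ages**: cohorts draw uniformly over [18, 34] GW — the real cohort age
  distribution is unknown, and a uniform design spreads information evenly
  over the range.
* **Determinism**: a phantom is a pure function of its spec (the seed
  drives only the speckle field); cohorts derive per-phantom seeds from
  the cohort seed.

What the phantoms do *not* emulate: anatomy beyond ridge/falx primitives,
acoustic wave propagation, probe-dependent resolution anisotropy, and
inter-subject biological variability of the HC–age relation. The last
point matters most for interpreting results: on phantoms the inner
circumference is a deterministic function of age, so the forest can invert
it almost exactly and held-out RMSE (~0.2 GW) is far below what any method
can achieve on clinical data, where the same design reports errors of
several days. Passing the phantom study demonstrates that the machinery —
surface fit, feature geometry, forest — is correct and well coupled, not
that clinical accuracy would match.

# Problem sizes and runtime choices

The shipped study configuration was chosen once as a desk-scale analogue
of the reference setup: phantom cohorts of 150 training and 30 test
volumes at 1.5 mm spacing (a full-width head at 0.6 mm exceeds a desktop
memory budget when 180 volumes are held simultaneously; features sample in
millimetres, so spacing only affects interpolation detail), surface-fit
validation on 128³ volumes at 0.6 mm, and the reduced forest (T = 8,
m = 50, depth 12). The 0.6 mm default of `phantom_spec()` is unchanged —
coarser spacing is requested explicitly by cohort builders.

# Known limitations

* The continuous refinement is block-coordinate, not a joint second-order
  solve; it trades convergence speed for guaranteed monotonicity. Very
  poor initializations (beyond the 15 mm pruning radius) fail with an
  explicit error rather than recovering.
* The self-intersection audit is the star-shape criterion; a fitted
  surface that folded while remaining simple would be flagged
  conservatively as failing.
* FA edge localization on thin shells carries a small inward bias
  (~0.5 mm at the default bank) that the fit inherits; sub-voxel accuracy
  targets are met, but the bias is visible in the acceptance numbers.
* The empty-admitted-set fallback at prediction (mean over all leaves) is
  a fixed convention, flagged in every prediction object.
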