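---
title: "Automated NEMA NU-2 IQ phantom analysis: models and methods"
author: "nemaiq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated NEMA NU-2 IQ phantom analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The NEMA NU-2 Image Quality phantom is a torso-shaped water tank holding
six hollow plastic spheres (inner diameters 10, 13, 17, 22, 28 and 37 mm,
walls about 1 mm) on a hexagonal ring.  PET/CT acceptance testing and
routine QA require spherical regions of interest (ROIs) at the physical
inner diameters, centered on each sphere.  Manual ROI placement is slow and
reader-dependent, and the smallest spheres are often barely visible in the
PET volume; sphere positions also change every time the phantom is
reassembled, and air bubbles regularly ride up the filling stems into the
spheres.  `nemaiq` localizes all six spheres automatically, using the CT
volume for geometric precision and the PET volume for contrast, and
reports sphere centers, ROI statistics and a PET-vs-CT misalignment
diagnostic.

## The matched-filter model

All detection steps use binary matched filters: a template mask of the
expected object (a filled sphere in PET, where the interior is hot, or a
hollow shell in CT, where only the plastic wall is bright) is slid across
the volume, and the sum or mean of the covered voxels forms a matched
value space whose maximum marks the best alignment.  Templates are
rasterized with the *Binary Center Inclusion Method*: a voxel belongs to
the template iff its center lies within or on the analytic boundary, with
ties included and no floating-point tolerance.  This rule makes template
voxel counts exactly enumerable, which the test suite exploits with
brute-force oracles.

Sub-voxel localization comes from quadratic interpolation of the matched
value space: around the grid maximum the largest box is taken whose X, Y
and Z profiles through the maximum are strictly concave (negative second
central differences at every interior point), an ordinary-least-squares
full quadratic is fitted over that box, and the analytic vertex (where the
fitted gradient vanishes) is the reported center.  If the fitted Hessian
is not negative definite the grid maximum is used and a warning attached.

## The ten-step pipeline

1.  **Coarse PET detection.**  Filled templates for the three largest
    spheres, largest first, scanned over the whole PET volume with the sum
    statistic; after each detection the covered voxels are zeroed so the
    same sphere cannot be found twice.  These estimates are integer voxel
    positions, accurate to about half a voxel.
2.  **Header mapping.**  The DICOM headers of both series express patient
    coordinates, so the header isometry is the identity on world
    coordinates; its inverse maps the PET estimates into CT voxels.
3.  **Large spheres in CT.**  A bounding box of two sphere diameters per
    axis is cut around each estimate; a hollow-shell template (inner
    diameter plus a 1 mm wall) is matched by the mean over non-air voxels
    (sum when no air was detected).  Shell voxels at the argmax, minus
    air, are labelled *plastic sphere wall*.
4.  **Wall model.**  The pooled mean HU of all wall-labelled voxels across
    the three large spheres, `muPSW`.
5.  **Hexagonal extrapolation.**  The spheres sit in descending-diameter
    order on a hexagon, so each small sphere faces its large partner
    across the center: `cH = c4 + c6 - c5` and the small-sphere estimates
    are the reflections `2 cH - c(i+3)`.
6.  **Small spheres in CT.**  Boxes of three diameters, integer-replicated
    up-sampling to below 1 mm per axis (no interpolation; the walls are
    only ~1 mm thick), air detection on the up-sampled values, then the
    rescaling `Vnew = -|Vold - muPSW|` so the shell filter rewards
    wall-like values instead of bright values, followed by the same shell
    matching and quadratic refinement.
7.  **Initial isometry.**  The unique proper rigid transform mapping the
    CT sphere-6 center exactly onto the PET estimate, the 6-5 line onto
    the 6-5 line and the 6-5-4 plane onto the plane; of the four symmetric
    candidates the one minimizing the total distance to the PET estimates
    is kept.  Collinear centers abort the analysis.
8.  **Six-sphere template.**  The union of six filled templates at the
    mapped (sub-voxel) CT centers on the PET grid.
9.  **6-DOF search.**  The initial isometry is perturbed over a 7-node
    grid per axis: rotations about the centroid of the mapped centers and
    translations, in 1 mm increments to +-3 mm (a rotation increment is
    1 mm of arc for the most-displaced sphere; the angular step is 1 mm
    divided by the largest distance of a mapped center from the rotation
    axis).  Each node's six-sphere template sum over the PET volume fills
    a 7^6 value space; a 6-D quadratic around the maximum yields the
    optimal isometry.
10. **ROIs and reports.**  Final PET centers are the optimal-isometry
    images of the CT centers; filled-sphere ROIs at the inner diameters
    give per-sphere and six-sphere-union mean/max; the displacement
    between the optimal and the header isometry at each sphere (`Di`,
    their norms, and the largest pairwise angle `thetaD`) quantifies
    scanner misalignment.  The report carries raw values only; judging
    whether a misalignment is acceptable is left to the user.

## Air-bubble compensation

Each CT subvolume is histogrammed into 10 equal-width bins between its
minimum and maximum.  Air (about -1000 HU) stretches that range so far
down that the dominant water peak lands in the upper half of the histogram
(bins 6-10); this is the detection rule.  When air is detected, voxels at
or below two population standard deviations under the subvolume mean are
labelled air and excluded from every matched-filter mean and from the wall
labelling.  Values exactly on a bin edge go to the higher bin, except the
maximum, which stays in bin 10.  The subvolume sizes (two diameters for
the large spheres, three for the small ones) keep water in the majority,
which this rule depends on; the synthetic phantom's body is torso-sized
for the same reason.

## Design choices in the 6-DOF refinement

Two choices here go beyond the ten steps above and deserve their
rationale:

* **Local 6-D fit.**  The 6-D quadratic is fitted over a 5^6 sub-box
  centered on the grid argmax (shifted inward at the search boundary),
  not over the full 7^6 space.  The matched-value surface is only
  near-quadratic close to its peak; when the peak sits 2-3 increments
  off-center -- routine, because the three-point initial isometry inherits
  up to half a PET voxel of rounding per coarse estimate and the hexagon
  geometry amplifies that across the ring -- a full-grid fit is dragged by
  the surface's flat tails and can misplace the vertex by millimeters.  A
  3^6 box is too small: the discrete template rasterization makes
  node-to-node values noisy, and 729 points spread over only three levels
  per axis amplify that noise.  The 5^6 box balances the two error
  sources; with it, randomized rigid-offset recoveries land within about
  0.5 mm.  This mirrors the concave-subset restriction that the 3-D fits
  always used.
* **Peak-centering iteration.**  The local quadratic fit is trusted only
  when the matched-value peak sits in the central +-1 node region of the
  sampled range; whenever the argmax falls further out (including on the
  range boundary, the search's own warning condition for an unreliable
  fit), `runPipeline()` re-centers the search on the current optimal
  isometry and repeats, up to three passes.  The initial isometry's
  rounding amplification can reach 4-6 mm at the spheres opposite the
  fitted triple, beyond a single +-3 mm pass, and even an interior peak
  2-3 increments off-center leaves the fit with residual bias.  Every
  pass is the standard search verbatim, and all warnings (including the
  first pass's boundary warning) are kept in the report.  The fitted
  vertex is also clamped to the sampled cube plus half an increment so a
  poor boundary fit cannot compose a wild transform.

## The synthetic phantom

`phantomConfig()` / `generatePhantom()` build paired CT and PET volumes
with exact ground truth:

* **Geometry.**  Six spheres (10-37 mm inner diameter, 1 mm walls,
  configurable winding and in-plane phase) on a 57.2 mm-radius hexagon
  inside an elliptical water body of semi-axes 147 x 110 mm and length
  100 mm -- torso-like proportions, large enough that every search
  subvolume stays inside water, as in the physical phantom.  The sphere
  plane sits at z = 1 mm by default: an arbitrary sub-voxel phase relative
  to both grids, as for a physically positioned phantom.  (Exactly z = 0
  would fall precisely halfway between PET slices of the default grid, a
  measure-zero alignment that no real phantom achieves and that
  artificially maximizes the coarse-detection rounding error.)
* **Rasterization.**  Sphere walls and bubbles are rendered as
  partial-volume fractions from a 4^3 sub-voxel sweep, so ~1 mm walls are
  representable on 1.37-2.73 mm grids; volumes are quantized to integers,
  matching the 16-bit DICOM pixel representation the writer uses.
* **Imaging.**  Isotropic Gaussian blur (defaults: 0.8 mm CT, 6 mm PET,
  the common post-reconstruction filter width) via padded FFT, then
  additive Gaussian noise (defaults 15 HU and 10% of the PET background).
  Noise is applied after the blur by default, emulating the smoothed
  texture of post-filtered iterative reconstructions; `noiseWhen =
  "before"` instead lets the blur act as the post-filter, which is the
  configuration used for the repeated-realization stability studies.
* **Bubbles.**  Spherical air regions clipped to the sphere interior,
  offset toward the sphere top (air collects as a cap against the upper
  wall).  Test fixtures place them tangent to the wall; a bubble floating
  mid-sphere would never touch the shell filter and could not bias
  localization.
* **Misalignment.**  A configured rigid transform moves the physical PET
  content while the PET header keeps nominal geometry, so the header
  isometry and the truth disagree by exactly the configured transform.
* **Determinism.**  The seed fully determines the output; the caller's
  RNG state is untouched.

What the generator does *not* emulate: the cold lung insert, scanner
point-spread-function ringing around the spheres, Poisson
projection-domain noise, CT beam hardening, and non-orthogonal
acquisitions.  Passing tests therefore demonstrate the algorithm's
geometric and statistical behavior under controlled, idealized imaging;
they do not certify performance under every clinical reconstruction.

## DICOM support

No DICOM reader is assumed; the package carries a minimal, purpose-built
explicit-VR little-endian reader/writer pair for single-frame series
(geometry tags, rescale slope/intercept, 16-bit pixels).  Slices are
sorted by the projection of Image Position (Patient) onto the slice
normal, robust to renumbered exports; inter-slice spacing inconsistent
beyond 1% or missing geometry tags abort the load.  Slice orientations
are accepted only when every direction cosine is -1, 0 or +1 (within
1e-6): oblique acquisitions terminate the pipeline rather than being
resampled.  The writer is cross-checked against an independent DICOM
implementation in the test suite.

## Numerical choices and degenerate inputs

* Voxel indices are 0-based, fractional, and refer to voxel centers; all
  reported centers are either fractional indices or mm world points.
* Matched-value ties take the first maximum in lexicographic (z, y, x)
  scan order, with a `MultipleMaxima` warning (symmetric noiseless inputs
  genuinely tie).
* The integer up-sampling factor is the smallest integer making the voxel
  size strictly less than 1 mm (2.5 mm -> 3; 2.0 mm -> 3, since 1.0 mm is
  not below 1 mm; 0.7 mm -> 1).  An up-sampled index `u` maps back to the
  parent grid as `(u + 0.5)/f - 0.5`.
* Bounding boxes use the minimal voxel count spanning `k` diameters,
  centered on the rounded estimate; boxes clipped at the volume edge
  shrink on the clipped side only and warn.
* Collinear sphere triples (isometry construction, hexagon extrapolation)
  abort with a classed error, as do empty templates, empty ROIs and
  volumes smaller than a template.
* The sample standard deviation (n-1) is the default for repeatability
  series; the population SD is used inside the 2-SD air rule, which is a
  property of one subvolume, not of a sample of realizations.

## Problem sizes used in validation

The repeatability studies in the test suite and the acceptance script use
50 noisy realizations for the CT and PET stability measurements (matching
the repeated-scan design they emulate), 12-20 randomized rigid offsets for
registration recovery, and single paired runs for the bubble-compensation
and misalignment checks.  The default grids are 228 x 174 x 48 CT voxels
and 114 x 86 x 36 PET voxels.

## Known limitations

* Accuracy is demonstrated against synthetic truth; on real scanners only
  precision (repeatability) is observable, and real reconstructions may
  add artifacts the generator does not model.
* The coarse PET stage assumes all six spheres are hot; cold-sphere
  configurations would need negated templates, which are not implemented.
* Background ROIs and the NEMA percent-contrast / background-variability
  computations are out of scope: the pipeline ends at the sphere ROIs.
* The misalignment report deliberately carries no pass/fail threshold.
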