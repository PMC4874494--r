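# nemaiq

Automated sphere localization and ROI analysis for PET/CT scans of the
NEMA NU-2 Image Quality phantom.

## What it does

The NU-2 IQ phantom holds six hollow plastic spheres (inner diameters 10,
13, 17, 22, 28 and 37 mm, ~1 mm walls) on a hexagonal ring inside a
torso-shaped water body. Quantitative PET QA needs 3-D spherical ROIs at
the physical inner diameters, centered on each sphere — but the small
spheres are hard to see in PET, sphere positions move every time the
phantom is reassembled, and air bubbles in the spheres bias naive
localization. `nemaiq` automates the whole analysis:

1. coarse detection of the three largest spheres in PET with binary
   matched filters (Binary Center Inclusion templates, iterated with
   zero-out suppression);
2. accurate sub-voxel localization of all six spheres in CT — hollow-shell
   matched filters, air-bubble detection (10-bin histogram mode rule +
   2 SD cut), a learned plastic-wall model `muPSW` with the rescaling
   `Vnew = -|Vold - muPSW|`, hexagonal extrapolation
   `cH = c4 + c6 - c5` to the small spheres, integer up-sampling, and
   3-D quadratic vertex refinement;
3. registration: the three-point initial isometry `PhiE` (sphere-6 center,
   6-5 line, 6-5-4 plane), a 7^6-node six-degree-of-freedom perturbation
   search (±3 mm, 1 mm increments) with a six-sphere template, and a 6-D
   quadratic fit giving the optimal isometry `PhiO`;
4. reporting: final PET centers `PhiO(c_i)`, per-sphere and
   six-sphere-union ROI mean/max, and the misalignment diagnostics
   `D_i = PhiO(c_i) - PhiDICOM(c_i)` with their norms and maximum pairwise
   angle `thetaD`.

A synthetic phantom generator (`phantomConfig()` / `generatePhantom()`)
produces paired CT/PET volumes with exact ground truth — blur, noise,
bubbles, winding variants and rigid PET-vs-CT misalignment — so the whole
pipeline is testable without scanner data. A minimal DICOM reader/writer
(explicit VR little endian, single-frame series) handles file-based
workflows.

## Worked example

Simulate a phantom whose PET content is shifted by a coherent
(8.6, 4.8, 4.8) mm scanner misalignment relative to its header, then run
the full analysis:

```r
library(nemaiq)

mis <- RigidTransform(diag(3), c(8.6, 4.8, 4.8))
cfg <- phantomConfig(misalignment = mis, seed = 23,
                     ctNoiseSd = 0, petNoiseSd = 0)
ph  <- generatePhantom(cfg)

res <- runPipeline(ph$pet, ph$ct)
print(res)
```

```
NEMA NU-2 IQ phantom analysis

Accurate PET centers (mm, PET world):
              x       y     z
sphere1  65.797   4.722 5.891
sphere2  37.198  54.254 5.734
sphere3 -20.047  54.227 5.765
sphere4 -48.504   4.750 5.857
sphere5 -20.082 -44.729 5.780
sphere6  37.219 -44.742 5.802

muPSW: 57.46 HU

ROI statistics:
 sphere     mean  max nvox
      1 2069.955 2701   22
      2 2466.872 3493   47
      3 2794.362 3901  105
      4 3040.161 3995  230
      5 3243.193 4000  471
      6 3418.839 4000 1092
union: mean 3261.3335, max 4000.0000 (1967 voxels)

thetaD: 0.60 deg; max |Di|: 10.93 mm
```

The ROI means climb from 2070 (10 mm sphere) toward the 4000-unit sphere
activity as partial-volume dilution from the 6 mm reconstruction blur
shrinks with sphere size — only the three largest spheres reach the full
4000 at their peak voxel. The misalignment block recovers the injected
|(8.6, 4.8, 4.8)| = 11.0 mm displacement with a sub-degree angular
spread: the signature of a coherent scanner misalignment rather than a
scaling problem. `muPSW` is the learned mean CT value of the
partial-volume plastic wall, well above water (0 HU) but below solid
plastic, as expected for ~1 mm walls on a 1.37 mm grid.

A command-line wrapper is included at `inst/scripts/niqa.R`
(`niqa.R run --pet <dir> --ct <dir> [--ct-geometry <json>]
[--no-air-detection] [--out <dir>]`, plus `simulate` and `repro`
subcommands).

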