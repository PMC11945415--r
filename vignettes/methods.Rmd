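---
title: "Non-contact head circumference from a single depth image: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-contact head circumference from a single depth image: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(headcirc)
```

## The measurement problem

Head circumference is the standard bedside indicator of brain growth in
newborns, taped in centimetres from the occiput around the brow. For
low-birth-weight infants in incubators, taping is stressful and risky:
the skin is fragile, access is restricted, and every manual intervention
disturbs the infant. `headcirc` implements a fully non-contact
alternative: a single top-down 16-bit depth image, taken through the
incubator canopy by an RGB-D sensor, is converted to a metric point
cloud, and the circumference is estimated from the visible head surface
plus one powerful prior — *the head rests on the mat*.

The top-down view never sees the lower part of the head. Rather than
attempting a 3D reconstruction of the occluded surface, the pipeline
summarizes the visible geometry relative to the bedding plane into three
features and lets a tree-ensemble regressor, trained against tape
measurements (here: analytic ground truth from a scene simulator), carry
the occlusion prior.

## Pipeline

1. **Detection.** Head and body bounding boxes come from a pluggable
   detector contract (`function(depth) -> boxes`). The clinical system
   uses an externally trained object detector; this package ships an
   oracle provider (synthetic scenes) and a file-based provider. No
   detector is trained here.
2. **Segmentation.** Boxes are turned into masks either by a
   depth-threshold fill against the background level or by box-seeded
   two-class refinement of the in-box depth histogram; masks are cleaned
   by morphological opening/closing (square element, default 5 px). The
   mat is the ring of valid-depth pixels around the body (default 40 px
   dilation), excluding body and head.
3. **Back-projection.** Each valid pixel (ud, vd) with depth zp maps to
   `x = -(zp/f) ud`, `y = -(zp/f) vd`, `z = zp` (mm) in the camera-origin
   frame. The synthetic renderer uses the exact algebraic inverse, so
   the convention is self-consistent.
4. **Mat plane.** The ring points are fit with `A x + B y + C z = 1` by
   least squares inside a RANSAC loop (minimal 3-point hypotheses,
   consensus counting, refit on the winning inlier set). This
   parameterization cannot express planes through the origin; the camera
   never lies on the mat, and degenerate configurations raise a classed
   error.
5. **Body frame.** The first principal component of the body cloud,
   projected into the mat plane, is the longitudinal axis; the vertical
   axis is the mat normal (camera side); the lateral axis completes a
   right-handed frame. The PCA sign ambiguity is resolved by the
   head-left convention: the head centroid must end on the negative
   longitudinal side.
6. **Head sphere.** The visible head surface is fit with a sphere in the
   linear standard form (`x^2+y^2+z^2 + kx + ly + mz + n = 0`), which is
   exact on noiseless spherical data even from upper-hemisphere-only
   samples. One trimmed refit discards points more than
   `sphere_trim_mm` (default 15 mm) off the fitted surface — those are
   depth artifacts, not anatomy.
7. **Cross-section.** The measurement plane is coronal: it contains the
   mat normal and the lateral axis and passes through the sphere centre,
   mirroring where a tape would run on a supine infant while staying
   insensitive to head orientation. Head points within a slab
   (half-width 2 mm) are expressed as (lateral position s, height above
   mat h), despiked against the fitted sphere, binned in s (1.5 mm),
   and summarized by the per-bin median.
8. **Features.** Three numbers in cm: the heights above the mat at the
   two lateral extremes of the visible curve (where the camera loses
   sight of the head — for a convex head this is essentially the
   widest, mid-height point) and the polyline arc length of the visible
   top. The mat-contact constraint makes these informative about the
   full perimeter: the hidden lower arc is pinned between the two
   visibility limits and the bedding.
9. **Regression.** A random forest (100 fully grown trees, all features
   considered at each split, seeded) maps features to circumference.
   Decision tree, extremely randomized trees and AdaBoost.R2 are
   available behind the same interface for comparison studies.

Every stage runs under a stage tag; any failure produces a report with
that tag (`$error$stage`) rather than a partial result, and the
effective configuration is embedded in each report.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `ransac_iterations` | 500 | – | plane hypotheses; sized for 640x480 clouds |
| `ransac_tolerance_mm` (pipeline) | 10 | mm | mat consensus band; see below |
| `ransac_tolerance_mm` (`fit_plane_ransac`) | 3 | mm | generic flat-surface default |
| `mask_kernel` | 5 | px | morphology element |
| `mat_ring_px` | 40 | px | mat ring width around the body |
| `slab_half_width_mm` | 2 | mm | section slab half-thickness |
| `bin_width_mm` | 1.5 | mm | lateral bin width (~1 pixel footprint) |
| `sphere_trim_mm` | 15 | mm | artifact rejection around the fitted sphere |
| `ntree` | 100 | – | ensemble size |

**Why the pipeline's mat tolerance is 10 mm.** Incubator bedding is not
flat: towels fold on the centimetre scale. A sinusoidal fold samples
densest at its crests, so a tight consensus band (3 mm) locks the
RANSAC plane onto a crest and biases *every* height in the scene by up
to the fold amplitude, with a sign that varies scene to scene. A band
that covers the fold amplitude (10 mm) makes the consensus set span the
folds, so the refit averages them into the stable mid-plane, while
genuine depth artifacts (tens of mm off the surface) are still
rejected. The generic `fit_plane_ransac` default stays at 3 mm, which
is appropriate for truly planar data with millimetre noise.

**Why sections are despiked against the sphere.** Specular and
transparency artifacts displace isolated pixels by 30–80 mm along the
ray. The per-bin median absorbs them in well-populated bins, but a
displaced point can occupy a bin of its own just beyond the true
lateral extent of the head, and the lateral extremes are exactly where
two of the three features are read. Points more than 15 mm off the
fitted sphere surface cannot be head surface (the true head deviates
from its spherical approximation by a few mm) and are dropped before
binning.

## The synthetic cohort

The simulator stands in for clinical data, which cannot be shipped. A
scene is a head ellipsoid and a body ellipsoid resting *tangent* on the
ideal mat plane (tangency is the invariant the whole method relies on;
it holds to better than 0.1 mm by construction), viewed by a 640x480
pinhole camera (f = 600 px) and rendered by exact ray casting with
z-buffering, then corrupted by Gaussian depth noise (sd 1 mm), 2%
outlier pixels displaced 30–80 mm, and a two-sinusoid mat undulation
(summed amplitude up to 8 mm) standing in for towel folds.

Heads are ellipsoids, not meshes, so the ground truth is analytic: the
coronal section through the centre is an ellipse whose perimeter is
computed by adaptive quadrature (it agrees with the Ramanujan
approximation to well under 0.01% at the anisotropies used). Cohorts
sample the circumference uniformly in 22–38 cm, the vertical/lateral
anisotropy in 0.85–1.15, head tilt up to 10 degrees per axis, body yaw
uniformly in 0–360 degrees, mat depth 850–950 mm, and mat tilt up to 2
degrees; scene sizes emulate low-birth-weight newborns. Every scene
carries its own derived seed, so a stored specification re-renders
bit-identically.

What the simulator does **not** emulate: real cranial shape (parietal
flattening, moulding), hair, bedding occlusions (tubes, blankets over
the head), detector localization error (oracle boxes are exact), and
the optical transmission of the canopy. Passing the synthetic
experiments therefore demonstrates that the geometry pipeline and the
feature/learning design recover circumference under controlled noise —
not clinical accuracy.

## The evaluation experiment

The packaged experiment mirrors the clinical protocol at desk scale:
184 scenes, split 135 training / 49 test by a seeded draw, a random
forest on the three features, and mean absolute error in cm as the
headline metric — MAE rather than (R)MSE because occasional large
misses (extreme poses) should not dominate a clinical summary; RMSE is
reported for diagnostics. The error distribution is binned at <=1 cm,
1–2 cm and >2 cm. `hc_compare()` runs all four algorithms on the
identical split. Under the default study conditions the random forest
achieves a held-out MAE well under 1 cm with about 80–90% of cases
within 1 cm; exact numbers for a given seed are reproduced by
`scripts/acceptance.R`.

Problem sizes throughout (184-scene cohorts at 640x480, 500 RANSAC
hypotheses on a 4000-point mat sample, 100-tree ensembles) were chosen
as the smallest that exercise the method at its native image scale.

## Numerical choices and degenerate inputs

* Plane and sphere systems are solved by QR least squares; rank
  deficiency (collinear points, coplanar sphere input, planes through
  the origin) raises `hc_error_degenerate` rather than returning
  nonsense. A non-positive squared radius is `hc_error_fit_failure`.
* RANSAC ties keep the earliest iteration and the sampler is seeded, so
  results are bit-reproducible; degenerate minimal samples are skipped
  and count towards the iteration budget.
* PCA alignment requires a 1.5 eigenvalue ratio between the first two
  principal axes; below that the pose is declared ambiguous.
* Missing depth is the sensor's 0 sentinel; NaN is normalized to 0 on
  ingest. Depth PNGs are written at 1 mm per grey level.
* Sections need at least 5 occupied bins; heights are clamped at zero
  in the feature vector (noise can push mat-grazing points marginally
  negative).
* The dome validation scene (`render_dome()`) makes the discretization
  limits of the section explicit: at 640x480 the lowest visible rim
  sample of a 50 mm hemispherical dome sits several mm above the mat
  (the surface is vertical at the rim, so a pixel footprint of
  1.3 mm in s maps to ~sqrt(2 r delta) ~ 6-8 mm in h), and the visible
  polyline arc is correspondingly a few percent short of the full
  semicircle. The feature extractor reports the visible geometry
  faithfully; it does not extrapolate to the contact point.

## Design choices where the design was open

* **Section plane orientation.** "Vertical plane through the sphere
  centre" admits any azimuth; the coronal plane (normal = longitudinal
  axis) is used because it matches the tape path on a supine infant and
  is the only azimuth that is anatomically stable across poses.
* **Left/right heights.** Defined as the (median-binned) height at the
  extreme occupied lateral bins of the visible curve — an operational
  reading of "height of the left and right sides of the head" that is
  well-defined for any convex head.
* **PCA input.** The body cloud only (not body+head): the head's mass
  would rotate the principal axis at strong tilts; configurable.
* **Extra features** (max height, section width, sphere radius) are
  off by default so the estimator matches the three-feature design;
  they can be enabled per config for ablation studies.
* **AP interpolation.** All-point (continuous) precision envelope, the
  practice of the detector family the clinical system uses; greedy
  confidence-ranked matching with at most one match per ground-truth
  box; IoU threshold 0.5 by default.
* **Train/test protocol.** A single seeded 135/49 split (no
  cross-validation), matching the scale of the clinical evaluation.

## Known limitations

* Features assume a convex, roughly ellipsoidal visible head; strong
  moulding or partial occlusion of the head violates this silently
  (the sphere-fit diagnostics are the guard: radius outside ~30–80 mm
  warrants suspicion).
* The regressor does not extrapolate: circumferences outside the
  training range are clamped towards it — a tree-ensemble property the
  clinical deployment must respect by training across the expected
  range.
* Heights inherit any residual bias of the mat plane; bedding whose
  roughness exceeds the RANSAC band (crumpled blankets under the head)
  degrades the left/right features first.
* Processing time is logged per stage but is hardware-dependent and is
  not part of any contract.
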