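# headcirc

Non-contact estimation of neonatal head circumference from a single
top-down 16-bit depth image.

## The problem

Head circumference (the occipitofrontal perimeter, taped in cm) is the
standard bedside indicator of brain growth in newborns. For
low-birth-weight infants in incubators, taping is stressful and risky:
the skin is fragile, access through the canopy is awkward, and every
manual intervention disturbs the infant. An RGB-D sensor mounted above
the incubator can capture the scene in one frame — but the camera only
sees the top of the head, so the tape path is largely occluded.

`headcirc` implements the measurement pipeline for this setting. It is
aimed at researchers in neonatal monitoring and 3D anthropometry who
want a fully testable, clinical-data-free implementation: a seeded scene
simulator with analytic ground truth stands in for ward data.

## The method

A depth pixel `(ud, vd)` (offsets from the principal point) with depth
`zp` back-projects through a pinhole camera with focal length `f` (px)
to metric coordinates

```
xp = -(zp / f) ud,   yp = -(zp / f) vd,   z = zp        [mm]
```

The pipeline then exploits one prior — *the head rests on the mat*:

1. head/body boxes from a pluggable detector; masks via depth fill or
   box-seeded refinement, cleaned morphologically;
2. mat plane `A x + B y + C z = 1` fit by least squares inside RANSAC
   on the ring of mat pixels around the body (the bedding undulates;
   the consensus plane is the stable height reference);
3. body frame by PCA (longitudinal = dominant principal axis projected
   into the mat plane; vertical = mat normal), head-left convention;
4. head sphere by linear least squares on
   `x^2+y^2+z^2 + kx + ly + mz + n = 0`, so the section position is
   insensitive to head orientation;
5. coronal cross-section through the sphere centre: head points within
   a 2 mm slab, expressed as (lateral position `s`, height above mat
   `h`), despiked against the fitted sphere and median-binned;
6. three features in cm — heights at the two lateral extremes of the
   visible curve and the arc length of the visible top — feed a seeded
   random forest (decision tree, extra trees and AdaBoost.R2 are
   available for comparison) that outputs circumference in cm.

Accuracy is summarized by the mean absolute error
`MAE = (1/n) * sum |y_i - yhat_i|` (cm) and the error distribution over
`<=1`, `1-2` and `>2` cm.

## Worked example

```r
library(headcirc)

# a synthetic cohort under the study conditions: depth noise 1 mm,
# towel-fold undulation up to 8 mm, 2% outlier pixels
cohort <- generate_cohort(60, seed = 42)
ds <- hc_extract_dataset(cohort)          # features + analytic truth
feats <- ds[, c("left_height_cm", "right_height_cm", "top_arc_length_cm")]

model <- hc_train(feats[1:45, ], ds$truth_cm[1:45], "random_forest")

# measure one held-out scene
sc <- cohort[[50]]
rep <- hc_measure(sc$depth, sc$spec$camera, detector_oracle(sc), model)
rep
#> Measurement report [scene]
#>   estimated head circumference: 36.16 cm
#>   features: left 7.18 cm, right 6.70 cm, top arc 16.54 cm
#>   mat plane inliers: 97.9%; sphere radius: 55.2 mm; section bins: 73
sc$circumference_cm
#> [1] 35.26283
```

The report says: the mat plane explained 97.9% of the ring points (a
reliable height reference), the fitted head radius (55 mm) is
anatomically plausible, and the estimate lands within 0.9 cm of the
analytic truth of 35.26 cm.
Held-out evaluation:

```r
ev <- hc_evaluate(predict(model, feats[46:60, ]), ds$truth_cm[46:60])
ev
#> Evaluation on 15 cases: MAE 0.764 cm (RMSE 0.962 cm)
#>   error <= 1 cm:  73.3%
#>   1 - 2 cm     :  20.0%
#>   error > 2 cm :   6.7%
```

A command-line front end with the same stages is installed as
`exec/headcirc` (`simulate | train | measure | evaluate | compare`);
scenes persist as 16-bit depth PNG + intrinsics/spec JSON + box
annotations, reports as JSON.

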