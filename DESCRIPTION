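Package: headcirc
Title: Non-Contact Neonatal Head Circumference from Top-Down Depth Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates neonatal head circumference from a single top-down
    16-bit depth image, as acquired through an incubator canopy with an
    RGB-D sensor. The pipeline back-projects the depth map to a metric point
    cloud, recovers the mat plane by RANSAC-robustified least squares,
    canonicalizes body orientation with principal component analysis, fits a
    sphere to the visible head surface, extracts a coronal cross-section
    referenced to the mat (exploiting the constraint that the head rests on
    the mat), and maps mat-referenced section features to circumference with
    a tree-ensemble regressor. A seeded synthetic scene simulator renders
    head and body ellipsoids on an undulating mat with sensor noise and
    outliers, providing analytic ground truth so every stage is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    EBImage,
    rpart,
    randomForest,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
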