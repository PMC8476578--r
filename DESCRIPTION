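Package: coordkin
Title: Head-Trunk Coordination Analysis for Immersive Steering and
    Joint-Angle Reproduction Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing head-trunk coordination from dual-segment
    Euler-angle recordings of an immersive first-person steering task and a
    joint-angle-reproduction (JAR) proprioception test. Implements course
    geometry (centripetal Catmull-Rom ideal paths, coin-plane crossing
    errors), segmentation with artifact rejection, a 50-variable descriptive
    kinematic battery (rotation amplitudes, angular speeds, head-torso
    correlations, anchoring indices, cross-correlation lags, dynamic time
    warping distances, spectral arc length, peak counts, speed ratios),
    outlier-downweighted principal component analysis for variable
    selection, repeated-measures inference with two-stage false discovery
    rate control, JAR proprioception metrics, and a synthetic-data
    generator with controlled coordination structure for end-to-end
    validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    nortest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
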