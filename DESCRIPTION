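Package: qsmgrad
Title: Principal-Axis Iron Gradient Mapping for Quantitative Susceptibility MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps spatial gradients of magnetic susceptibility (a proxy for
    tissue iron) along the principal orthogonal axes of subcortical nuclei.
    Regions of interest are decomposed by singular value decomposition of
    their voxel coordinates, partitioned into equidistant segments by
    parallel hyperplanes, and summarised as per-segment median
    susceptibility functions. Includes motor-subtype and disease-stage
    classification rules for Parkinson cohorts, hemispheric lateralization,
    covariate-adjusted group comparison with multiplicity correction,
    partial correlation with clinical scores, and a synthetic cohort
    generator that emulates the statistical structure of such studies for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    nortest,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
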