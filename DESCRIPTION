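Package: searchlight
Title: Searchlight Multivoxel Pattern Analysis and Voxel-Based
    Morphometry for Gray-Matter Volume Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Whole-volume searchlight multivoxel pattern analysis (MVPA)
    of structural gray-matter maps: cube-neighbourhood support vector
    machine classification under leave-one-out cross-validation with
    nested hyperparameter selection, exact binomial conversion of
    accuracy maps to p-value maps, connected-component cluster
    extraction, covariate-adjusted post hoc voxel-wise tests with
    permutation-based cluster-level family-wise-error control,
    whole-brain voxel-based morphometry (VBM) group contrasts, and
    cross-validated ROC evaluation of region-mean features.  A
    synthetic-cohort generator emulating smoothed, modulated gray-matter
    maps with seeded group effects and covariate structure supports
    validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
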