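Package: connsel
Title: Connectivity-Guided Voxel Selection and Split-Half Pattern Decoding
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether distal functional connectivity indexes
    local multivoxel pattern discriminability in task fMRI. The package
    simulates block-design cohorts with planted seed-coupled connectivity,
    category-specific multivoxel patterns and controllable univariate
    activation; estimates run-wise GLM beta and t maps; computes seed-based
    functional connectivity on task-regressed, band-passed residuals; selects
    most-connected, least-connected, most-activated and activation-matched
    voxel sets under a leave-one-split-out scheme; scores split-half
    correlation decoding; and performs group inference with repeated-measures
    ANOVA, paired t tests and sign-flip permutation maps enhanced by
    threshold-free cluster enhancement.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Software, StatisticalMethod, FunctionalConnectivity
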