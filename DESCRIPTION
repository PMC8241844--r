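Package: lesionmap
Title: Multivariate Support-Vector-Regression Lesion-Symptom Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate lesion-symptom mapping of registered binary stroke
    lesion masks against behavioral outcome scores using epsilon support
    vector regression (SVR-LSM). Provides minimum-overlap analysis masking,
    voxelwise nuisance regression of lesion volume, cross-validated
    hyperparameter search, back-projection of the SVR dual solution into a
    voxelwise feature-weight map, permutation-based voxel p-values with
    cluster-extent family-wise-error correction, intersection certainty
    against probabilistic white-matter tract atlases, and a synthetic
    lesion-cohort generator with a ground-truth critical region for
    end-to-end validation at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    kernlab,
    lhs,
    yaml,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
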