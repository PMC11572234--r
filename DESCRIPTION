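Package: wmhshape
Title: Three-Dimensional Shape Analysis of White Matter Hyperintensities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies the three-dimensional shape of white matter
    hyperintensity (WMH) lesions on co-registered binary MRI masks.
    Lesions are classified into periventricular/confluent and deep types
    by their distance to the lateral ventricles (3 mm and 10 mm inflated
    ventricle masks), and per-lesion shape markers (solidity, convexity,
    concavity index, box-counting fractal dimension, eccentricity) are
    averaged per participant. Linear and logistic regression helpers
    relate baseline shape markers to longitudinal cerebrovascular
    outcomes. A synthetic phantom and cohort generator makes every
    pipeline stage testable without access to clinical imaging data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    igraph,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
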