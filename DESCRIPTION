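Package: radrepro
Title: Reproducibility Screening of Radiomic Features Under Delineation Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multi-observer, multi-modality tumor delineation on
    synthetic CT-like phantoms and screens radiomic features for robustness to
    delineation variability. Implements a 107-feature radiomic bank
    (first-order, shape, GLCM, GLRLM, GLSZM, GLDM, NGTDM) with fixed-bin-width
    discretization, peritumoral ring construction on anisotropic voxel grids,
    quartile coefficient of dispersion (QCD) and two-way random-effects
    intraclass correlation (ICC) reliability screening, tumor versus peritumor
    group comparison, and PCA dimensionality reduction with a variance
    retention criterion.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
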