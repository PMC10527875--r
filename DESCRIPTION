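Package: mrishift
Title: Quantifying Scanner-Induced Domain Shift in Multi-Center Structural MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures the degree of domain shift (site and scanner effects) in
    multi-center structural MRI cohorts from the images alone.  Twenty-two
    no-reference quality features are extracted slice-wise from the spatial,
    frequency, wavelet and grey-level co-occurrence texture domains of each
    NIfTI volume, and the resulting per-scan feature table is analysed with
    kernel maximum mean discrepancy, cross-validated domain classification,
    random-forest feature-importance ranking and 2-D embeddings (t-SNE, UMAP).
    A synthetic multi-site phantom generator emulating per-site noise,
    contrast, smoothing, bias-field and resolution differences makes the whole
    pipeline testable without any imaging data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    EBImage,
    e1071,
    randomForest,
    Rtsne,
    uwot,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
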