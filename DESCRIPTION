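Package: latentCNA
Title: Single-Cell Copy Number Calling via Latent-Space Cross-Cell Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers single-cell copy number alteration (CNA) profiles from
    low-coverage single-cell DNA sequencing bin read counts. Read counts are
    quality-filtered and normalized into log2 read counts (LRC), each genomic
    bin is embedded into a low-dimensional latent space with an autoencoder
    trained across cells, breakpoints shared by cells are detected by circular
    binary segmentation of the latent sequence, and per-cell integer copy
    numbers and ploidy are estimated with an EM-fitted Gaussian mixture model
    over segment LRC that includes an explicit baseline-shift parameter.
    Includes a clonal-tree count simulator with ground truth and the
    evaluation metrics (breakpoint distance, breakpoint ratio, MAD, ACN)
    used to validate callers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Rsamtools,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
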