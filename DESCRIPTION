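Package: mrdseq
Title: Measurable Residual Disease Quantification by Immunosequencing and
    Analytical Validation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for tracking malignant B-cell clonotypes across
    immunosequencing samples and quantifying measurable residual disease
    (MRD), together with the statistical machinery used to analytically
    validate such an assay: probit limit of detection, Sadler
    precision-profile limit of quantitation, nonparametric limit of blank,
    random-effects variance-component precision analysis, polynomial-method
    linearity assessment, and nested-bootstrap quantitation-bias estimation.
    Includes a synthetic-data module that generates healthy repertoires,
    malignant clones, contrived dilution samples, blank panels, and factorial
    validation grids with Poisson template sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
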