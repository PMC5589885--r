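Package: ctcquant
Title: Quantification of Circulating Tumor Cells from Imaging Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream quantification for negative-depletion circulating
    tumor cell (CTC) enrichment experiments analysed by imaging flow
    cytometry. Provides a ground-truthed synthetic data generator
    (population sampling, single-cell multichannel image rendering, and a
    stochastic enrichment-cascade simulator), threshold-based single-cell
    sizing and membrane-mask expression measurement, MESF fluorescence
    calibration with optional size-bias correction, rule-based rare-cell
    classification (CTC identification and four-class contaminant
    deconvolution), and population-level statistics (quantile threshold
    derivation, below-threshold fractions, size-by-expression quadrants,
    expected-yield curves, rank-sum comparisons, and enrichment-run
    accounting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
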