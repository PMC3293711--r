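Package: regnorm
Title: Normalization Assessment for Two-Channel Regulation Microarrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluation of normalization strategies for two-channel
    ChIP-on-chip and MeDIP-on-chip ("regulation") microarrays. Implements
    six normalization methods (LOWESS, quantile, VSN-style calibrated
    generalized-log, T-quantile, Tukey's biweight scaling, Peng's rotation
    method), a ROC/AUC metric of the separation between negative-control
    and gene-promoter probe log-ratio distributions, a two-component
    Gaussian mixture model of the log-ratio distribution, an ACME-style
    sliding-window upper-quantile enrichment finder, a synthetic-data
    generator with known ground truth, and an end-to-end comparison
    pipeline. Reads NimbleGen-style pair files and writes GFF p-value
    tracks and BED region calls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    limma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC,
    mclust,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
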