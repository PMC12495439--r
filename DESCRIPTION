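Package: icombat
Title: Incremental Empirical-Bayes Batch Effect Correction for DNA
    Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Location/scale batch-effect correction for DNA methylation
    array data (ComBat-style empirical Bayes shrinkage of per-site batch
    means and variances), together with an incremental mode that corrects
    newly measured batches against the frozen global parameters of an
    earlier fit, so that previously corrected samples are bit-identical
    before and after integration.  Includes M-value/beta-value transforms,
    a serializable fitted-model store, a simulation generator for
    EWAS-style benchmark scenarios, and evaluation metrics (per-site group
    regression, TPR/FPR, genomic-control inflation factor, PCA, surrogate
    variable counting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    sva,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
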