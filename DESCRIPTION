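Package: pairaudit
Title: Systematic Bias Auditing for Paired-Input Biological Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to benchmark pair classifiers (such as sequence-based
    protein-protein interaction predictors), interrogate their
    generalizability across datasets, identify representational
    node-degree bias with dedicated feature, node-degree, recurrence and
    debiasing auditors, and eliminate it via node-balanced negative
    subsampling. Includes sequence k-mer, conjoint-triad and
    autocovariance feature extractors, a pairwise min-product kernel,
    in-network and out-of-network split construction, and a seeded
    synthetic-data generator that plants controllable degree bias versus
    genuine motif signal so every auditor verdict has a known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    kernlab,
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
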