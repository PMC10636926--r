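Package: trisomyDE
Title: Simulation and Trisomy-Aware Differential Expression for Aneuploid RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Negative-binomial simulation of disomic and trisomic gene-count
    matrices and a self-contained, instrumentable differential-expression
    engine (median-of-ratios size factors, gene-wise dispersion estimation
    with asymptotic trend fitting and empirical-Bayes shrinkage, MLE and
    MAP log2 fold changes, Wald tests with configurable fold-change null,
    Benjamini-Hochberg adjustment). Provides naive and trisomy-aware
    analysis modes (ploidy normalization matrix; dosage-informed null
    hypothesis) to study how standard pipelines can fabricate apparent
    dosage compensation on trisomy 21 data simulated with none, plus a
    sweep harness over replicates, sequencing depth and dispersion
    hyperparameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
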