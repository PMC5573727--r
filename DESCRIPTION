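Package: elmseq
Title: Expression-Level Monitoring by Methylation-Sensitive Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of Dam-methylase reporter screens read out by
    methylation-sensitive restriction digestion (DpnI/MboI) and deep
    sequencing. Turns raw amplicon reads from randomized promoter and
    5'-UTR libraries into per-variant expression estimates (the DAMRatio),
    classifies variants by a Gaussian-mixture model over log10 ratios,
    and provides the downstream sequence analyses: positional log2
    odds ratios, motif-group comparisons, mutual-information epistasis
    against a resampling null, folding-energy window scans, naive Bayes
    and support-vector expression predictors, transcription start site
    calling from gene-specific 5'-end RNA-seq, and plate-reader growth
    slopes. A generative simulator with planted ground truth emulates
    the full experiment for validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
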