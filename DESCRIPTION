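Package: degrecap
Title: Recapitulation of Bulk RNA-Seq Differential Expression by
    Downsampled Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how robustly single-cell RNA-seq identifies
    differentially expressed genes as a function of cell number,
    sequencing depth, and DEG characteristics (p-value, fold change,
    transcript abundance). Provides a negative-binomial simulator of
    paired bulk and single-cell experiments with gene-level ground
    truth, pseudo-bulk aggregation, TPM quantification, log
    normalization, a DESeq2-style negative-binomial Wald test with
    median-of-ratios normalization, a Wilcoxon rank-sum marker test on
    log-normalized cells, cell subsampling and count-level read
    thinning, and an evaluation grid reporting DEG overlap,
    quartile-stratified recapitulation rates and Spearman correlations
    of p-values across sampling levels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
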