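Package: scMPKit
Title: Meta-Program Discovery and Tumour Ecosystem Analysis for
    Multi-Sample Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting intratumoral heterogeneity from
    multi-sample single-cell RNA-seq: expression-based copy-number
    inference with CNV-score/correlation malignancy calling, per-sample
    consensus non-negative matrix factorization (cNMF) with stability-based
    rank selection, aggregation of per-sample programs into cross-sample
    meta-programs, rank-based (UCell-style) per-cell signature scoring,
    single-sample gene-set enrichment, ligand-receptor permutation testing,
    signature-matrix NNLS bulk deconvolution, and ecosystem-level
    correlation and survival statistics. Ships a synthetic-data generator
    that plants known programs, CNV clones, interactions and outcomes so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    cluster,
    methods,
    rlang,
    stats,
    survival,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    jsonlite,
    knitr,
    optparse,
    pracma,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
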