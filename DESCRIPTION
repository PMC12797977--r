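Package: ihtseq
Title: Integrated Hypothesis Testing for Bulk RNA-Seq Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Differential-expression analysis of bulk RNA-seq count matrices
    using an integrated hypothesis testing strategy: per-gene Student t-tests
    and permutation median-difference tests are combined with Stouffer's
    method, adjusted by the Benjamini-Hochberg procedure, and gated on log2
    fold change. Includes strict expression filtering, trimmed mean of
    M-values (TMM) normalization with log2-CPM transformation, one-sided
    Fisher's exact gene-set over-representation with radar-chart value
    export, a delta-delta-Ct relative quantification helper for qPCR, a
    negative-binomial count simulator with ground-truth labels for pipeline
    validation, and a configuration-driven end-to-end runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
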