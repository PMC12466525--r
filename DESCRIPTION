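Package: CoexRewire
Title: Differential Co-Expression Networks and Regulatory Impact Factors
    for Two-Condition RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to contrast gene co-expression networks between two
    experimental conditions from bulk RNA-seq counts. Implements a
    negative-binomial Wald test for differential expression, regulatory
    impact factor (RIF1/RIF2) scoring of transcription factors against
    the differentially expressed gene set, per-condition co-expression
    network inference with the partial-correlation and information-theory
    (PCIT) edge-elimination rule, differential node connectivity
    z-scoring between the two networks, hypergeometric over-representation
    analysis, and preranked gene set enrichment analysis with permutation
    normalized enrichment scores. Ships a synthetic two-condition count
    simulator with planted differential expression and planted
    transcription-factor rewiring so that every stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    igraph,
    optparse
Config/testthat/edition: 3
biocViews: GeneExpression, Network, NetworkInference,
    DifferentialExpression, GeneSetEnrichment, Transcriptomics
RoxygenNote: 7.3.3
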