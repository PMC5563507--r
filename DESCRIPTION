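Package: tfregnet
Title: Transcription Factor Regulatory Network Inference from ChIP-Seq and
    Knockout Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates transcription-factor ChIP-seq peak sets with
    knockout-versus-wild-type differential-expression tables to infer
    direct/indirect activation/repression regulatory networks, using a
    summit-within-5-kb gene-association rule. Builds putative cis-regulatory
    modules (pCRMs) by transitive peak merging with occupancy clustering,
    computes TF-pair cooperative-regulation summaries and quadrant
    concordance, and provides pre-ranked gene set enrichment analysis with a
    weighted Kolmogorov-Smirnov statistic and gene-set permutation null. A
    synthetic-data generator plants ground-truth networks so every stage is
    validated end to end against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    fgsea,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
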