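Package: CAGEstack
Title: Multi-Scale Reproducible TSS Peak Calling from CAGE Data
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers reproducible transcription start site (TSS) peaks at
    multiple genomic scales from CAGE (cap analysis of gene expression) tag
    data. Single-nucleotide CAGE TSS (CTSS) counts are clustered into the
    full laminar hierarchy of maximal-scoring segments over all density
    parameters (Paraclu-style density clustering), each cluster is scored by
    its hierarchical stability, replicate cluster sets are merged by
    reciprocal overlap and filtered with the irreproducible discovery rate
    (IDR) copula mixture model, and the broadest ("bottom") and narrowest
    ("top") reproducible peaks are tested for two-condition differential
    expression with a negative-binomial exact test. Includes a
    negative-binomial CTSS simulator with planted peak architectures and
    planted differential expression for end-to-end validation, promoter
    annotation against gene TSS models, and a legacy single-scale
    clustering mode for side-by-side comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
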