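Package: prokannot
Title: Integration of Multi-Evidence Prokaryotic Genome Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns raw per-tool evidence for a newly sequenced microbial
    genome - gene calls from several ab initio predictors, ranked homology
    hits against multiple protein databases, and protein domain scans - into
    one consolidated annotation. Merges predictor output into a consensus
    gene set after masking RNA genes, assigns one product name per CDS while
    minimizing hypothetical names, votes a best-supported taxonomy per contig
    from top homology hits with an alignment-length tie-break, summarises
    annotations as hierarchical (Krona-style) trees, core-gene completeness
    and pathway tallies with hypergeometric list enrichment, and benchmarks a
    gene set against a reference using identical / similar-within-50-bp /
    not-detected categories. Ships a deterministic synthetic-data generator
    so the whole pipeline is testable without external databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    BiocGenerics,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
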