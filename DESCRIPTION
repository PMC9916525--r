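Package: pluriMine
Title: Candidate Pluripotency Gene Mining from Reprogramming Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate pluripotency genes from bulk RNA-seq count
    data of induced pluripotent stem cell (iPSC) lines reprogrammed from a
    fibroblast baseline, as in unreplicated multi-line designs (e.g. one
    Bactrian camel fetal fibroblast sample against seven clonal iPSC lines).
    Provides per-line exact conditional differential expression against the
    baseline, hypergeometric gene-set enrichment over six KEGG/GO annotation
    levels, enrichment-driven and known-inducible-gene-driven screening groups
    with count-threshold filtering, protein-protein-interaction component and
    degree filters for core-gene extraction, per-line top-k supplementary
    ranking, cross-species ortholog-mapped set comparison, and a seeded
    negative-binomial synthetic-data generator with planted ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
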