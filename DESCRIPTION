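Package: lncSigMatch
Title: Connecting Drugs and Diseases Through lncRNA Expression Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Repurposes coding-gene microarrays for long non-coding RNA
    (lncRNA) expression analysis and connects diseases to candidate drugs via
    lncRNA signatures. Probe sequences are reannotated against an annotated
    transcriptome by exact full-length matching with a four-stage filter chain
    (perfect match, cross-biotype exclusion, gene-level collapse, minimum
    probe support). Treatment/control instances yield per-instance log2
    fold-change signatures; differentially expressed lncRNAs are merged into
    drug-induced lncRNA sets. Query lncRNA lists are scored against the sets
    by hypergeometric over-representation analysis (ORA), and two-class
    expression profiles by lncRNA set enrichment analysis (LSEA), a
    GSEA-style running-sum statistic with a permutation null yielding ES,
    NES, nominal p, FDR q and FWER p values. A seeded synthetic-data
    generator provides fixtures with known ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    fgsea
Config/testthat/edition: 3
biocViews: Transcriptomics, Microarray, GeneSetEnrichment, Annotation
RoxygenNote: 7.3.3
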