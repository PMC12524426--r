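Package: crhub
Title: Cis-Regulatory Hub Analysis from Chromatin Activity and 3D Contacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links distal regulatory elements to target genes with the
    activity-by-contact (ABC) model, assembles cis-regulatory hubs (CRHs) as
    connected components of the bipartite promoter/element graph, calls
    topologically associating domains (TADs) with the directionality index,
    aggregates contact maps over loop lists (APA), and compares hubs and
    enhancer-gene co-regulation between two conditions such as control versus
    CTCF-depleted cells. Ships a synthetic-data generator that plants hubs,
    TAD boundaries, loops, and co-regulation effects so that every stage of
    the pipeline can be validated against known ground truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
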