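Package: binclust
Title: OTU Delineation and a Persistent Barcode Index Registry for COI
    DNA Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assigns COI DNA-barcode sequences to operational taxonomic
    units (OTUs) by refined single-linkage clustering: single-linkage
    grouping at a fixed p-distance threshold followed by Markov-clustering
    refinement with Silhouette-based model selection. Scores the
    concordance of any partition against prior taxonomy (MATCH, SPLIT,
    MERGE, MIXTURE categories and the clustering F-measure), maintains a
    persistent OTU registry with stable BOLD-style identifiers,
    merge/split lifecycle and an audit trail, and ships a synthetic
    barcode-dataset generator with controlled intraspecific variation and
    nearest-neighbour divergence for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    seqinr,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    ape,
    cluster,
    withr
Config/testthat/edition: 3
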