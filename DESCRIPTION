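Package: hublinker
Title: Regulatory Hub Discovery and Enhancer-Target Assignment from
    CTCF Loops, Accessibility and Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds group-consensus peak sets from replicated CTCF and
    ATAC-seq peak calls, filters CTCF-HiChIP loops to consensus-anchored
    loops with sufficient read support, assembles loop anchors into
    regulatory hubs (connected components of the anchor graph) seeded by
    disease-risk linkage-disequilibrium blocks, models each hub gene's
    log-CPM expression as a function of the other hub genes and the hub's
    ATAC peak accessibility with all-relevant (Boruta-style) feature
    selection under a repeated-run stability filter, and reports putative
    causal regulatory elements inside risk LD blocks together with their
    predicted target genes. Includes a synthetic-data generator with
    planted element-to-gene effects so every stage is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    yaml,
    optparse
Config/testthat/edition: 3
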