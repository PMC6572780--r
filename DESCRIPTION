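Package: petloop
Title: Chromatin Interaction Calling, Annotation and Network Analysis for ChIA-PET
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning mapped ChIA-PET paired-end tags (PETs) into
    high-confidence chromatin interactions and downstream biology: replicate
    pooling and deduplication, self-ligation filtering, hypergeometric
    interaction scoring with Benjamini-Hochberg correction, proximal/distal
    anchor annotation against gene models, distal regulatory region
    identification, expression integration (activity calls, promoter-pair
    co-expression against distance-preserving shifted controls, Shannon-entropy
    tissue specificity), two-tissue comparison of interactions and expression,
    chromatin interaction network (ChIN) components with annotation-term
    enrichment, and a fully deterministic synthetic-data generator with a
    ground-truth manifest for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
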