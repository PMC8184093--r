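Package: bibliomine
Title: Intelligent Bibliometrics for Biomedical Literature Mining
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for profiling a biomedical research field
    from its literature. Parses MEDLINE-format publication records and
    PubTator entity annotations, builds Jaccard-normalized co-occurrence
    networks of terms and institutions with modularity-based community
    detection, tracks topic evolution over a document stream by detecting
    semantic drift against topic centroids and spawning descendant topics
    (scientific evolutionary pathways), and prioritizes genes in a
    heterogeneous disease-chemical-gene-variant network via entropy-weighted
    centrality combination and a disease-specificity intersection ratio.
    Includes synthetic corpus generators with planted ground truth so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
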