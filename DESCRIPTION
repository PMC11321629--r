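Package: diseaseMapper
Title: Multi-Dimensional Disease Similarity Mapping by Consensus of
    Distance Metrics and Data Dimensions
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds disease-to-disease similarity maps from bipartite
    disease-feature association data observed in several data dimensions
    (associated genes, pathways, medicating drugs, symptoms, and two
    chemical layers). For each dimension six set distance metrics
    (Euclidean, Hamming, cosine, Jaccard, Sorensen-Dice, overlap) are
    combined into one matrix by hierarchically averaging them along a
    dendrogram built from their pairwise Ipsen-Mikhailov spectral
    distances; the per-dimension matrices are fused into a consensus map
    by the same rule. Downstream tools cover ward.D2 clustering with
    Dunn-index model selection, classical multidimensional scaling,
    Fisher exact feature enrichment with Bonferroni correction, disease
    neighborhood and shared-feature queries, and comparison against the
    ICD-10 coding hierarchy. A synthetic-data generator with planted
    multi-view cluster structure makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
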