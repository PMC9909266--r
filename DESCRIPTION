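Package: germdiv
Title: Germplasm Diversity Analysis with Dominant Markers, Morphology and Color
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infrastructure for genetic-diversity studies of germplasm
    collections scored with dominant PCR markers (SRAP, SCoT and similar
    band-presence fingerprints) alongside mixed morphological traits and
    CIELab color phenotypes. Provides S4 containers for band matrices,
    primer panels, trait tables and color tables; per-band and per-primer
    informativeness statistics (gene diversity, polymorphic information
    content, effective multiplex ratio, marker index, discriminating
    power, resolving power); ecological diversity indices (Shannon-Wiener,
    Gini-Simpson, Pielou evenness); Euclidean, Gower, binary and
    correlation-based dissimilarities; UPGMA clustering with cophenetic
    validation; tanglegram entanglement with rotation-based untangling;
    principal component analysis of trait matrices; and a seeded
    synthetic-panel simulator with known group structure for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    ape,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Clustering, Genetics, PrincipalComponent, Visualization
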