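Package: dipscan
Title: Domain Insertion Profiling Analysis for Sort-Seq Surface-Expression Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for massively parallel domain-insertion
    profiling of membrane proteins read out by two-gate fluorescence-activated
    sorting and sequencing. Calls insertion junctions from paired-end reads,
    computes log-ratio surface-expression enrichment normalised to an internal
    flexible-linker control with Poisson standard errors and REML-weighted
    replicate combination, derives recipient and donor biophysical features
    (elastic-network stiffness and fluctuations, windowed amino-acid scale
    sums, contact counts, backbone dihedrals, solvent accessibility),
    classifies insertion positions and donor motifs by clustering, and fits an
    interpretable random-forest compatibility model with drop-feature
    importance, accumulated local effects, and pairwise interaction strength.
    A synthetic sort-seq generator emulates the full experiment so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    bio3d,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    mclust,
    metafor,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
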