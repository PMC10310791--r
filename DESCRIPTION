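Package: plastichic
Title: Cell-Cycle-Aware Analysis of Single-Cell Hi-C Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-cell Hi-C (scHi-C) contact maps in
    proliferating tissues, where cell-cycle and replication signatures dominate
    conformational variation. Provides per-cell quality control and cell-cycle
    phasing from contact-distance statistics, derivation of strict-early and
    strict-late genomic reference sets, A-compartment and early-replication
    scoring of genomic bins, S-phase-seeded clustering of cells, a
    replication-trend mixture model that jointly infers cell clusters, a latent
    S-phase progression coordinate (s-score) and cluster-specific per-bin
    replication regimes, an MCMC contact-matrix shuffler with a k-nearest-
    neighbour enrichment scorer, locus-level map statistics (insulation,
    virtual 4C, hotspot scanning, funnel-anchor profiling), and integration of
    enhancer, Polycomb and ATAC accessibility data with differential contact
    maps. A synthetic-cohort generator with planted ground truth supports
    offline testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mclust,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
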