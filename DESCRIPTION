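Package: allohot
Title: Allosteric Hotspot Discovery from Deep Mutational Scanning and
    Structure-Based Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies allosteric hotspot residues in allosteric
    transcription factors from sort-seq deep mutational scanning count
    tables (replicate-aware dead-variant calling, weighted positional
    scoring, upper-quartile hotspot designation, ligand-contact
    exclusion), computes a 27-feature structural and physicochemical
    description of every residue from dimer coordinates (contact maps,
    long-range-interaction clustering, Gaussian network model
    correlations, contact-network centrality, solvent accessibility),
    ranks features by F score and Jensen-Shannon divergence, and selects
    discriminative feature combinations with a genetic algorithm wrapped
    around a cross-validated shallow neural network, including
    cross-protein prediction and transfer learning across homologs.
    Ships a synthetic-data module that emulates sort-seq libraries, toy
    dimer structures and homolog feature families so the whole pipeline
    is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    data.table,
    igraph,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
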