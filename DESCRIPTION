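Package: kinpocket
Title: Kinase Binding-Site Annotation, Interaction Fingerprints and
    Conformation Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for consistent annotation of protein kinase catalytic
    domains: mapping structures onto the canonical 85-residue binding-site
    numbering, anchor-based superposition onto a master structural frame,
    7-type x 85-residue kinase-ligand interaction fingerprints, DFG and
    alphaC-helix conformation classification, grid-probe subpocket
    assignment, conserved water-cluster assignment, a 0-10 structure
    quality score, and a query engine over annotated collections. Includes
    a synthetic fixture generator that builds kinase-like complexes with
    known ground truth so every pipeline stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    rpart,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
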