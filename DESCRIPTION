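Package: mavkit
Title: Discovery and Evolutionary Analysis of Maverick (Polinton) Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for mining Maverick/Polinton virus-like transposable
    elements in genome assemblies and analysing their evolution. Implements
    translated homology scanning with colocalization rules, terminal
    inverted repeat (TIR) and target site duplication (TSD) mapping with
    iterative position-weight-matrix refinement, intact versus fossil
    classification of element copies, alignment quality statistics,
    orthologous-insertion detection with lognormal age calibration,
    cophylogenetic event inference by approximate Bayesian computation with
    event-cost tree reconciliation, and branch-wise dN/dS codon models with
    likelihood-ratio tests. A synthetic-data module generates genomes,
    elements, trees and codon alignments with known ground truth so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    igraph,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
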