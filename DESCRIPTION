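Package: TripletFold
Title: RNA Secondary Structure Prediction with an Extended Nearest-Neighbor
    (Triplet) Energy Model
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Minimum free energy structures, partition functions, Boltzmann
    ensembles and melting curves for single-stranded RNA under both the
    classical nearest-neighbor (NN) stacking model and an extended
    nearest-neighbor (ENN) model in which free energies are attached to
    triples of consecutive base pairs. Triplet stacking energies are inferred
    from Turner-style stack tables by a maximum-entropy iterative
    proportional fitting procedure and converted back to free energies by
    inverse Boltzmann calibration. The dynamic-programming engine fills the
    constrained partition-function arrays and their min-plus twins in
    compiled code, supports stochastic traceback sampling and exact structure
    counting, and ships brute-force enumeration oracles plus
    sensitivity/PPV benchmarking utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: StructuralPrediction, Software, Thermodynamics
RoxygenNote: 7.3.3
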