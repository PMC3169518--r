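Package: hairpintse
Title: Transition-State Ensemble Analysis for Two-State Peptide Folding
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis of two-state beta-hairpin folding
    trajectories: native-topology order parameters (the R inter-strand
    distance parameter, the fraction of native sidechain contacts Q, and
    Calpha RMSD), two-dimensional free-energy landscapes by Boltzmann
    inversion with subset-based error estimates, decomposition of the
    landscape into folded, unfolded and transition states, transition-state
    residence-time kinetics with path-scenario classification, and
    structural characterization of the transition-state ensemble through
    characteristic backbone and sidechain distance distributions. Includes
    a synthetic trajectory generator with three-state Markov kinetics and
    toy hairpin geometries that provides ground truth for every estimator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
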