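Package: tmcpnn
Title: Transmembrane Helix Prediction with Counter-Propagation Neural
    Networks and Helix Geometry Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts alpha-helical transmembrane regions from protein
    sequence alone using a two-stage chemometric pipeline: overlapping
    20-residue windows are encoded as amino-acid adjacency-matrix
    descriptors and classified by a counter-propagation neural network
    (a supervised Kohonen map); runs of transmembrane-labelled windows
    are collapsed to consensus regions by a central-residue rule; and
    region boundaries are refined with a position-specific amino-acid
    preference matrix built from annotated transmembrane termini. Also
    provides a helix-geometry toolkit (ideal alpha-helix construction
    from internal coordinates, backbone dihedrals, Kabsch superposition
    and RMSD series, Ramachandran histograms, helical-wheel hydrophobic
    moments and radial distribution functions) for assessing predicted
    helices, plus a seeded synthetic membrane-protein generator so the
    whole pipeline is trainable and testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
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
LinkingTo:
    Rcpp
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
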