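Package: ifplast
Title: Coarse-Grained Modelling of Intermediate Filament Subunit Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bead-chain models of intermediate filament (IF) dimers and
    tetramers, a Lennard-Jones hexagonal-lattice substrate with an
    adhesion-energy calibration procedure, overdamped Langevin sampling of
    subunit conformations in solution and during deposition onto the
    substrate, worm-like-chain and conformational observables (end-to-end
    length, Kabsch RMSD, projection area, coarse-grained SASA, persistence
    length), plus a synthetic atomic-force-microscopy scene generator and a
    height-map morphometry pipeline (flattening, segmentation,
    filament-contact exclusion, area statistics and exponential fits).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
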