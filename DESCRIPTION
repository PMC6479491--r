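Package: rinflow
Title: Residue Interaction Networks and Essential Dynamics for Protein Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-simulation analysis of protein conformational ensembles:
    stability metrics (superposed RMSD, per-residue RMSF, Shrake-Rupley
    solvent-accessible surface area), geometric hydrogen-bond detection and
    per-residue occupancy, essential dynamics (covariance-based principal
    component analysis with cosine-content admissibility and free-energy
    landscapes by Boltzmann inversion), minimum-energy representative
    selection, and weighted residue-interaction-network centrality analysis
    (degree, closeness, Brandes betweenness) with between-state difference
    maps. Includes a synthetic-ensemble generator with known, parameterised
    properties so every stage is testable without external trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
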