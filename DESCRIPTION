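Package: beadmc
Title: Coarse-Grained Constant-pH Monte Carlo of Protein Self-Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: One-bead-per-residue rigid-body Metropolis Monte Carlo for
    protein solution behaviour. Builds a coarse-grained model from an
    all-atom PDB structure, samples protonation states at constant pH with
    Debye-Hueckel screened electrostatics, estimates the orientation-averaged
    potential of mean force between two proteins and the reduced second
    osmotic virial coefficient B2*, decomposes the protein-protein
    interaction into electric multipole terms, and simulates many-body
    cluster (oligomer) formation with Hamiltonian parallel tempering,
    reporting cluster size distributions and relative shape anisotropy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
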