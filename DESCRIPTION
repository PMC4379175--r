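Package: ringtail
Title: Localizing Disordered C-Terminal Tails of Ring Chaperonins from
    Coarse-Grained Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for localizing the disordered C-terminal tails of
    ring-shaped chaperonins such as GroEL from molecular-dynamics trajectories:
    frozen-core Langevin simulation of a Cn-symmetric ring, per-segment
    residue-residue contact maps, aggregation and max-normalization,
    ring-symmetry block summation, terminal-residue contact profiles, and
    projection of per-residue scores onto structure via the B-factor column.
    Includes a seeded clash-avoiding builder for missing C-terminal residues,
    Kabsch superposition with iterative outlier rejection, and a coarse-grained
    bead-spring trajectory generator with designed attraction sites that serves
    as a ground-truth test bed for the whole analysis chain.
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
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
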