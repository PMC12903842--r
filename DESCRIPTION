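Package: anomertraj
Title: Anomer-Selective Hydrogen-Bond and Fluctuation Analysis of
    Transporter Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis for molecular-dynamics "flooding"
    simulations of sugar transporters exposed to mixtures of alpha- and
    beta-glucose. Detects geometric protein-ligand hydrogen bonds,
    computes per-residue anomer preference ratios with threshold
    classification and membrane-region summaries, compares bond-share
    proportions between mixed- and single-anomer conditions, builds
    sliding-window RMSF matrices and between-condition difference maps,
    tracks ligand permeation along the membrane normal with
    residency-time filtering, and ships a synthetic toy-transporter
    generator with known ground truth so every stage is testable without
    external trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
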