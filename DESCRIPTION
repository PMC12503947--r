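Package: compotts
Title: Two-Layer Cellular Potts Simulations of Cell Competition
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates competition between two epithelial cell types by
    coupling a cellular Potts physical layer (contact energies plus area
    elasticity evolved by Metropolis-Hastings lattice dynamics) to a
    probabilistic decision layer: crowding-damped target-area growth, a
    G1-sizer / S-G2-M-timer cell cycle with division along the cell's
    semi-major axis, density-dependent and contact-dependent apoptosis
    hazards, and live-cell extrusion. Provides generators for mechanically
    relaxed confluent two-type tissues with a central mutant colony,
    replicate and parameter-sweep drivers, net-growth-rate fitness
    estimation and outcome classification, deterministic checkpoint and
    resume, and lattice snapshot rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
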