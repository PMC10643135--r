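Package: redoxmap
Title: Geometry and Spectroscopy of Redox Cofactor Chains in Membrane Pumps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative structural analysis of redox-driven ion pumps of
    the Na+-NQR (sodium-pumping NADH:quinone oxidoreductase) type. Reads
    atomic models in PDB/mmCIF format, recognises redox cofactors (flavins,
    iron-sulfur clusters, quinones) and measures edge-to-edge distances;
    converts distances to empirical electron-tunneling rates with the
    Moser-Dutton ruler; quantifies rigid-body domain motions, transmembrane
    helix tilts and crosslink distance compatibility between conformational
    states; classifies ion-binding sites from first-shell coordination
    geometry; profiles channel radii along a pathway with a probe-sphere
    optimiser; and simulates and fits zero-field Moessbauer doublets and
    multi-component powder EPR spectra. A synthetic-fixture generator builds
    structures and spectra with exactly known ground truth so every analysis
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
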