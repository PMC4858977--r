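Package: coopbind
Title: Mechanistic Models of Cooperative Heterodimer-DNA Binding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Equilibrium mass-action modelling of ternary transcription
    factor-DNA complexes, built around the PPARgamma:RXRalpha heterodimer
    binding its PPRE response element. Enumerates the full species network of
    two ligands on a two-site DNA element, solves it at equilibrium, fits
    one-site and two-parameter heterodimer binding constants from titration
    data, quantifies cooperativity (omega factors, the pathway-invariant
    heterodimer-on-DNA constant K_DoD, binding free-energy differences and
    the sigma affinity-ratio proxy), converts per-variant constants into
    energy-based position-specific scoring matrices, and evaluates motif
    predictive power by log-odds scanning and ROC/AUC on labelled regions.
    Includes a synthetic-data generator emulating microfluidic (MITOMI-style)
    fluorescence binding measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
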