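Package: mitotime
Title: Mechanistic Cell-Cycle Models, Snapshot Pseudo-Time and Parameter
    Estimation
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for mechanistic modelling of the mammalian cell cycle
    as interlinked bistable mass-action switches (restriction point, G1/S,
    G2/M and metaphase/anaphase transitions) merged into a stably
    oscillating core model, with optional DNA-damage checkpoint and
    nucleus/cytoplasm compartmentalisation.  Includes steady-state
    continuation with fold and Hopf detection, synthesis of asynchronous
    single-cell snapshot data (exponential age density on the limit cycle,
    affine antibody-style observation, multiplicative noise), circular
    pseudo-time reconstruction (Gaussian-mixture clustering plus an exact
    shortest circular tour), rank-to-time conversion for asynchronous
    populations, local-level Kalman smoothing, and global parameter
    estimation by enhanced scatter search with a gradient-free dynamic
    hill-climbing local solver.  Estimation problems can be read from and
    written to a PEtab-style folder of TSV tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    mclust,
    lhs,
    jsonlite,
    xml2,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
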