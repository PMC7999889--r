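Package: cvm2d
Title: Two-Dimensional Cluster Variation Method on Zigzag Toroidal Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the two-dimensional cluster variation method (CVM) on
    a zigzag-offset toroidal grid of bistate (on/off) units. Counts the
    configuration variables (single units, nearest-neighbor pairs,
    next-nearest-neighbor pairs, and horizontal triplets), computes the CVM
    reduced enthalpy, entropy, and free energy, evaluates the closed-form
    equilibrium solution in the interaction-enthalpy parameter h, and brings
    arbitrary binary grid topographies toward a free-energy minimum by
    stochastic like-for-unlike node-pair swapping. Includes generators for
    random, rich-club-like, and scale-free-like initial topographies, a
    plain-text grid format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
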