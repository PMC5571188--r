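Package: levybasin
Title: Stochastic Basins of Attraction for Piecewise-Smooth Vegetation
    Dynamics under Alpha-Stable Levy Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stability analysis of the metastable forest state in a
    conceptual Amazonian vegetation model with a discontinuous growth
    switch.  Provides the Filippov convex-inclusion treatment of the
    discontinuous drift, its smooth approximation by Gaussian (Friedrichs)
    mollification, Euler-Maruyama simulation of the resulting scalar SDE
    driven by symmetric alpha-stable Levy motion, finite-difference
    solvers for the nonlocal mean-first-exit-time and escape-probability
    boundary-value problems with exterior (volume) conditions, and
    stochastic basins of attraction under an escape-probability criterion
    and a mean-exit-time criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
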