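Package: turingcap
Title: Turing Patterns of the Schnakenberg System on a Sphere with a Hole
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses Turing pattern formation of the
    Schnakenberg activator-inhibitor system on the unit sphere and on
    spherical caps (the sphere minus a geodesic disc modelling a yeast bud
    scar). Provides deterministic cap meshing, closed-form linear stability
    theory including perturbed Laplace-Beltrami eigenvalues for small holes,
    a piecewise-linear surface finite-element solver with semi-implicit
    (1-SBEM) time stepping and a discrete Laplace-Beltrami eigensolver,
    spherical-harmonic projection of final patterns, density-based pole
    detection and pattern metrics, and replicate-ensemble orchestration with
    percentile summaries and slope significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    pracma,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    withr,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
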