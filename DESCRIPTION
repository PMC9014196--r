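Package: msccov
Title: Moments of Pairwise Coalescence Times and F(ST) Under the
    Multi-Species Coalescent
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exact first and second moments, covariances and expected shared
    branch lengths of pairwise coalescence times under the multi-species
    coalescent on rooted bifurcating species trees with piecewise-constant
    diploid population sizes and no post-divergence gene flow.  Translates
    these into moments of average pairwise sequence differences (dX, dY, dXY
    and the net divergence d) under the infinite-sites model, and into
    Taylor-series approximations for the expectation, bias and variance of
    the sequence-based F(ST) estimator, the island-model gene-flow transform
    <Nm>F, and two divergence-time linearizations.  Includes a seeded Monte
    Carlo gene-tree simulator with infinite-sites mutation overlay that
    serves as an independent oracle for every exact quantity, and a small
    command-line front end for config-driven scenario sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
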