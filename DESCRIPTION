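Package: jointshape
Title: Correspondence-Based Statistical Shape Modeling and Articular
    Analysis of Bone Joints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for correspondence-based statistical shape modeling of
    articulating bones and for joint-level morphometrics. Reads and writes
    triangulated bone surface meshes (PLY), mirrors left-side bones,
    smooths, decimates and clips meshes, aligns cohorts by iterative
    closest point registration and generalized Procrustes analysis, builds
    cross-subject correspondence-particle models, extracts principal-
    component shape modes with parallel-analysis retention and +/- k SD
    surface warps, estimates discrete mean and Gaussian curvature,
    delineates articular regions by second principal curvature, and
    computes articular coverage by surface-normal ray intersection,
    joint-space distance maps, and the Ateshian congruence index, with
    population statistics reported at correspondence particles. A synthetic
    joint and population generator with analytic curvature and gap oracles
    makes every stage testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
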