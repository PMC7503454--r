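Package: mionmap
Title: Simulation and Analysis Pipeline for Block-Design MION fMRI of
    Object Novelty and Value
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and analyzes block-design contrast-agent (MION)
    monkey fMRI experiments that map object novelty and learned value.
    Provides a seeded synthetic-data generator (16-block base/probe
    designs, sign-inverted MION hemodynamics, planted per-network
    effects, spatially autocorrelated noise, graph-structured resting
    covariance), voxelwise GLM estimation in percent-signal units,
    Monte-Carlo cluster-extent familywise correction under a mixed
    Gaussian/mono-exponential spatial autocorrelation model, PC-stable
    partial-correlation graph inference with spectral partitioning into
    functional networks, joint novelty/value null-contour
    classification, a compact bilinear dynamic causal model with a
    balloon hemodynamic forward model and Laplace model evidence, and
    the scan-count power formula for MION block designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    rlang,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
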