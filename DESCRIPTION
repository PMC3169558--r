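Package: dendrofield
Title: Two-Field Spiking Network Simulator with Dendritic Plateau Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-dimensional cortical sheet as a pair of overlaid
    lattices: a somatic field of adaptive quadratic integrate-and-fire
    (Izhikevich) units and a dendritic field of slow Morris-Lecar units
    producing all-or-none plateau potentials, coupled by fixed random
    Gaussian-kernel connectivity and regulated by a single global inhibitory
    unit. Provides stimulus protocols (constant drive, Gaussian white-noise
    current, transient global inhibition, targeted line excitation, random
    dendritic pulse trains), spatial spike-raster metrics (Gaussian-smoothed
    snapshots, lag-dependent inner products and their exponential decay
    constants, spatial clustering indices, bump trajectories, core
    principal-axis skewness), and a config-driven experiment runner for
    studying mobile, immobile and broken modes of localized bump activity
    under noisy background input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
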