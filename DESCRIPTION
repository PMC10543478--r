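Package: gridpop
Title: Population Autocorrelation Analysis of Grid Cell Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and characterizing hexagonal grid-cell
    lattice structure from neural recordings in undersampled environments
    such as circular tracks. Implements occupancy-normalized smoothed rate
    maps, 2D spatial autocorrelograms and their sum across comodular cells
    (the population autocorrelation), gridness scoring and lattice
    spacing/orientation inference from the autocorrelogram peak ring,
    field-shuffle null models with permutation significance, hierarchical
    partitioning of cells into grid modules, track linearization with 1D
    autocorrelation, and cross-environment rate-map correlation tests. An
    idealized grid-cell simulator (sinusoidal-grating rate maps, random
    phases, synthetic trajectories, inhomogeneous Poisson spiking) is
    included for validation and end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
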