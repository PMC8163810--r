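Package: CanopyCarbon
Title: Canopy Structure and Aboveground Carbon Dynamics from Repeat Lidar
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the impact of wind disturbance (blowdowns)
    on tropical forest canopy structure and aboveground carbon density (ACD)
    from repeat lidar surveys. Converts lidar-style point returns into canopy
    height models by Delaunay triangulation or gridded first-return means,
    fits the top-of-canopy-height to biomass power allometry by Gaussian
    maximum likelihood with Monte Carlo uncertainty propagation, detects
    canopy gaps as 8-connected components and estimates the discrete
    power-law (Zeta) gap size-frequency exponent by Metropolis-Hastings MCMC,
    projects the equilibrium canopy height distribution from a height-class
    transition matrix with a Dirichlet-multinomial posterior, performs linear
    spectral mixture analysis for change detection in optical imagery, and
    book-keeps recovery time of pre-disturbance carbon stocks. A synthetic
    landscape generator makes the full pipeline testable end to end without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    interp,
    sp,
    igraph,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'CanopyCarbon-package.R'
    'raster-grid.R'
    'raster-io.R'
    'canopy-rasters.R'
    'acd-model.R'
    'disturbance-detection.R'
    'gap-analysis.R'
    'height-transitions.R'
    'synthetic-data.R'
    'recovery.R'
    'pipeline.R'
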