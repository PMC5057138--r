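Package: topopump
Title: Organic-Matter Transport and Deposition over Cold-Water Coral Topography
Version: 1.0.0
Authors@R: person("Maarten", "Verhoeven", email = "m.verhoeven@example.org",
    role = c("aut", "cre"))
Description: Offline reaction-transport modelling of suspended organic matter
    over cold-water coral (CWC) carbonate mounds and ridges. Vertical velocity
    is diagnosed from the flux divergence of horizontal currents on a
    terrain-following (sigma) Arakawa C-grid, organic carbon is advected with
    a mass-conservative first-order upwind scheme together with passive
    sinking, decays at a first-order rate, enters through a constant surface
    export flux, and is removed at the seabed by settling that is enhanced
    over coral habitat to represent suspension feeding. Includes a synthetic
    generator for shelf-slope bathymetry with Gaussian mounds and a
    shelf-break ridge, transport-conserving tidal flow with a spring-neap
    envelope, and a coral habitat mask, plus analyses of deposition versus
    depth by habitat class, organic-matter focusing factors, vertical-velocity
    extrema and scenario comparisons (baseline, no filtration, no
    hydrodynamics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ncdf4,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
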