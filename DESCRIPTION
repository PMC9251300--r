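Package: cyanoagg
Title: Coupled Aggregation and Vertical Transport of Colony-Forming
    Cyanobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates the colony-size dynamics of buoyant, colony-forming
    cyanobacteria (such as Microcystis aeruginosa) in a stratified lake
    water column.  Size-resolved colony classes aggregate through physical
    collision kernels (Brownian motion, turbulent shear, differential
    settling) following discrete Smoluchowski coagulation dynamics, while
    being advected by light-regulated buoyancy and dispersed by
    depth-dependent turbulence.  The coupled advection-dispersion-reaction
    system is solved with an explicit finite-volume upwind scheme on a 1D
    grid with no-flux boundaries.  Includes a synthetic water-column
    profile generator for high- and low-wind regimes, diagnostics for
    colony appearance times and total-concentration profiles, and a
    concentration-sweep driver with power-law fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
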