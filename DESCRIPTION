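Package: mtpolarity
Title: Microtubule-Based Spontaneous Cell Polarity: Stochastic Simulation and Mean-Field Theory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A minimal activator-depletion model of spontaneous cell polarity
    driven by dynamic microtubules. Microtubules nucleated from a central
    centrosome undergo dynamic instability, stall at the cell boundary, and
    deliver a conserved, membrane-stabilizing polarity factor whose local
    membrane density feeds back on the microtubule boundary-release rate
    through a Hill-type dose-response. The package provides the closed-form
    mean-field steady state of the microtubule population, the dispersion
    relation and phase boundaries of the linear stability analysis of the
    membrane reaction-diffusion equation, a seeded 2D particle-based
    stochastic simulator (microtubules and polarity factors as explicit
    particles) with an exact inverse-CDF sampler for diffusion on the circle,
    polar order-parameter observables with drift correction and
    noise-floor controls, and conversions between the binding-affinity
    half-length and lattice binding-density conventions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
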