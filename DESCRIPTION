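Package: ReactorLifelines
Title: Lagrangian Lifeline Analysis for Bioreactor Scale-Down Design
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical analysis of microbial lifelines (per-organism
    substrate-exposure time series) in large-scale fed-batch fermentors,
    aimed at the rational design of scale-down simulators. Implements a
    Monod/Herbert-Pirt kinetic model of Penicillium chrysogenum with
    dynamic penicillin-production regulation, an ideal-mixing reference
    state, a stochastic compartment-network lifeline generator emulating
    the circulation statistics of a 54 m3 stirred vessel, turbulence
    filtering, metabolic-regime classification with transition-pattern
    and residence-time statistics, intra-limitation arc analysis,
    composite Fourier spectra, and long-horizon product-rate population
    responses via lifeline stitching.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    utils,
    S4Vectors,
    SummarizedExperiment,
    deSolve,
    signal,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    zoo,
    optparse
Config/testthat/edition: 3
biocViews: Software, TimeCourse, CellBiology
RoxygenNote: 7.3.3
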