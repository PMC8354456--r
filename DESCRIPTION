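Package: wormKS
Title: Keller-Segel Modeling of Starved C. elegans L1 Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for a Keller-Segel chemotaxis
    model of aggregation in starved first-stage (L1) Caenorhabditis elegans
    larvae. Worm density evolves by a Fokker-Planck equation whose drift is
    the gradient of a potential combining Weber-law responses to a
    short-range self-secreted attractant and a long-range repellent with a
    crowding (excluded-area) term; the signals obey linear
    reaction-diffusion equations. Provides fourth-order periodic
    finite-difference spatial operators, stiff adaptive time integration
    with a velocity-based step cap, linear stability analysis (dispersion
    relations, instability thresholds, fastest-growing modes, Neumann disk
    eigenmodes), scenario drivers with geometric Brownian noise injection,
    radially summed Fourier power-spectrum pattern quantification, scalar
    diagnostics, and an overdamped Langevin particle simulator that serves
    as an individual-based cross-check of the continuum model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Rcpp, stats, utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse, png, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
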