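Package: robnet
Title: Structural Robustness Analysis of Qualitative Biomolecular ODE Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds qualitative models of biomolecular reaction networks from
    property-tagged interaction terms (sigmoidal, saturating, threshold and
    unbounded kinetics), instantiates them with seeded random parametric
    function families, and verifies robustness claims numerically: positive
    invariance of the nonnegative orthant, Nagumo boundary certificates for
    constraint sets and sectors, piecewise-linear Lyapunov decrease and
    exponential decay rates, multistart equilibrium detection with stability
    classification and componentwise ordering, and detection of conserved
    moieties. Ships five worked gene-regulatory and signaling networks
    (L-arabinose feedforward loop, sRNA-mRNA silencing, cAMP-PKA signaling,
    lac operon, MAPK cascade with positive feedback) together with
    ensemble-based robustness suites.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
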