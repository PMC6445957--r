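Package: angiosprout
Title: Agent-Based Simulation of VEGF- and Notch-Driven Sprouting Angiogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid agent-based / ordinary-differential-equation simulator of
    sprouting angiogenesis on a 2-D lattice. Endothelial-cell agents carry a
    detailed intracellular signaling model (Dll4-Notch1 lateral inhibition,
    NICD-controlled transcription, VEGFR1 decoy kinetics and VEGFR2
    activation) integrated by forward Euler, coupled to diffusing
    extracellular fields of VEGF-A and soluble VEGFR1. Includes skeleton-based
    vessel-network metrics (relative vessel area, branch points per
    millimeter), tip-cell timing statistics, and drivers for receptor
    knockout scenarios, single-parameter sensitivity sweeps and
    cell-to-cell heterogeneity experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    xml2,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
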