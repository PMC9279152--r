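Package: persisterdyn
Title: Population Dynamics and Fluctuation Analysis of Drug-Tolerant
    Persister Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how cancer cell populations survive
    lethal drug exposure through a reversible persister state, and for
    measuring mutation rates of persister cells with a two-step
    fluctuation assay.  Implements a deterministic transition-to-persister
    population model with drug-dependent death and switching rates,
    Bayesian parameter inference with BIC/AIC model selection across
    switching-rate variants, a stochastic birth-death-switch-mutate
    branching-process simulator of multiwell fluctuation experiments,
    analytic estimators of spontaneous and persister mutation rates based
    on mutant establishment probabilities, and Poisson versus
    Luria-Delbruck dispersion analysis of per-well persister abundance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
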