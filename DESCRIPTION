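Package: T6SSim
Title: Agent-Based Simulation of Type VI Secretion System Warfare and
    Resistance Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A 2-D agent-based simulator of contact-dependent killing between
    rod-shaped bacteria via the type VI secretion system (T6SS). Cells are
    elongating spherocylinders that grow, divide, and mechanically relax on an
    unbounded plane; attackers fire toxin-loaded needles at Poisson-distributed
    times, and targets accumulate toxin doses that deplete a scalar integrity
    variable according to per-toxin sensitivities and an optional pairwise
    toxin-interaction matrix. On top of the spatial engine the package provides
    head-to-head competition experiments (competitive advantage, absolute
    fitness, extinction, cross-protection sweeps) and mutate-select-replace
    evolutionary trajectories with both agent-based and simplified analytic
    selection backends, used to predict when phenotypic resistance to single-
    and multi-toxin T6SS arsenals can evolve.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
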