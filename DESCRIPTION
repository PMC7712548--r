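Package: crownpore
Title: Rate-Theory Analysis of Ion Transport Through Atomically Thin
    Biomimetic Pores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinetic and energetic analysis of single-ion transport through
    sub-nanometre pores in atomically thin membranes, modelled on the
    graphene crown-ether (18-crown-6) pore. Provides construction, tilting
    and discrete-gradient analysis of one-dimensional free-energy profiles;
    an overdamped Brownian-dynamics walker with one-way incoming-rate
    curves; a three-site one-way kinetic chain with deterministic steady
    state, transient ODE solution, closed-form current and an exact
    event-driven (Gillespie) simulator; back-of-the-envelope physical
    estimators for capture, drift-feed, association and dissociation rates
    and for pore plus access resistance; diffusion-limited regime criteria
    and voltage-window bounds; weighted nonlinear fitting of the kinetic
    model to current/occupancy tables; and a synthetic-data generator that
    emulates ion-counting molecular-dynamics observables with replica
    counting noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
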