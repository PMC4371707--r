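Package: cbreach
Title: Cerebellar Context-Correction Learning for Equilibrium-Point Reaching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of a cerebellar learning architecture for reaching in
    three dimensions. A four-degree-of-freedom arm actuated by eleven Hill-type
    muscles is driven by an equilibrium-point (threshold-control) central
    controller; a cerebellar microcomplex stores sensorimotor contexts in which
    the reaching error increased, together with corrective muscle commands, and
    replays those corrections anticipatively through radial-basis-function
    recall. Complex spikes that trigger storage are generated either by an
    inferior-olive model with subthreshold oscillations gated by the visual
    error, or by per-muscle proprioceptive rules, giving four model variants.
    An idealized point-mass central-force model with impulsive corrections is
    included to study the stability of the scheme via angular-momentum
    reduction. Tools are provided to run multi-reach learning experiments and
    summarize performance as integrated hand-target error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
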