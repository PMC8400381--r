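Package: ralogic
Title: Integrative Signed Networks and Boolean Dynamics for Rheumatoid
    Arthritis Signalling
Version: 0.1.0
Authors@R:
    person("Genhotel", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds an integrative, executable network for rheumatoid
    arthritis signalling by fusing a transcription-factor co-regulatory
    network with a mechanistic signalling network, projecting
    treatment-response differential expression and disease-variant
    overlays onto it, extracting executable subnetworks, and analysing
    them with Boolean dynamics: exhaustive fixed-point enumeration,
    asynchronous attractor classification, model reduction, virtual
    knock-outs, stochastic dose-response simulation, and constraint-based
    reconstruction of monotone logical rules from stable-state tables.
    Ships a 13-variable TNF/IL6/TGFB1 signalling fixture together with
    seeded synthetic-data generators so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
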