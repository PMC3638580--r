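Package: pathflux
Title: Pathway Network Efficiency and Flux Models for Multi-Target
    Compound Screening
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to evaluate compound efficacy against a signalling
    pathway modelled as a directed weighted network. Multi-target docking
    scores are transformed into edge-weight perturbations of the target's
    outgoing edges; network efficiency (the sum of reciprocal weighted
    shortest-path lengths over ordered node pairs) and network flux (its
    restriction to paths ending at designated exit nodes) quantify the
    predicted impact of each compound on signal propagation. Compounds are
    ranked by the relative decrease of these metrics and correlated with
    experimental activity. Ships a curated approximation of the platelet
    aggregation pathway, reference docking scores for nineteen platelet
    targets, an antiplatelet activity table for twenty-one compounds, and
    seeded generators for scale-free pathway-like networks and docking-score
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Network, Pathways, SystemsBiology, GraphAndNetwork, Cheminformatics
RoxygenNote: 7.3.3
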