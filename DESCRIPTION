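Package: cmpa
Title: Candidate Mechanism Perturbation Amplitude Scoring for Causal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the up- or down-regulation of a causal disease-mechanism
    network from gene-level log2 fold changes. A mechanism is a signed directed
    graph of BEL-style causal statements converging on a central node; each hub
    receives an Impact Factor (its own weight plus the signed sum of incoming
    values) and the Candidate Mechanism Perturbation Amplitude (CMPA) score is
    the sum of Impact Factors over all hubs. Includes readers for edge-list,
    GraphML and JSON node-link networks, causal-edge filtering, mechanism
    extraction around a central node, a permutation null distribution of scores
    with a one-sample Student's t-test and an empirical p-value, synthetic
    mechanism and weight generators with an independent recursive scoring
    oracle, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
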