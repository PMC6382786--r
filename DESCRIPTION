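Package: kinnet
Title: Kinship-Driven Social Networks Across the Demographic Transition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Agent-based simulation of multi-generation pedigrees under
    Poisson fertility, construction of mixed kin/friend social networks
    with a fixed personal degree, structural summaries (local clustering,
    graph distance, k-step neighbourhood sizes), and gossip-based
    reputation dynamics with optional forgiving. Includes replicate sweep
    drivers, PED-like and GraphML input/output, and deterministic pedigree
    fixtures for closed-form kin arithmetic.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
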