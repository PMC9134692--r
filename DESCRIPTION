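Package: hyperpaths
Title: Shortest Hyperpaths and Hyperpath Enumeration in Directed
    Hypergraphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Algorithms for source-sink hyperpaths in general directed
    hypergraphs, the natural model of cell-signaling reaction networks
    where a reaction takes a set of reactants to a set of products.
    Provides B-connectivity reachability (forward reachability from a
    source, backward traceability from a sink, and the doubly-reachable
    restriction), an efficient Dijkstra-like heuristic for shortest
    source-sink hyperpaths that properly handles cyclic hyperpaths, an
    exact exhaustive enumeration of all source-sink hyperpaths via
    out-set constrained subproblems, validation of superpath and
    hyperpath certificates including cycle detection, seeded synthetic
    hypergraph generators, a plain-text tab-separated edge-list format,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
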