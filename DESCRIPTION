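Package: brnest
Title: Parameter Estimation for Qualitative Biological Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Logical-parameter synthesis for multivalued (Rene Thomas)
    biological regulatory networks. Enumerates every parametrization of a
    network (optionally restricted by declared parameter ranges), builds the
    asynchronous state graph for each candidate, verifies biological
    observations written in Computation Tree Logic (CTL) with a built-in
    explicit-state fixpoint model checker, and returns the accepted
    parametrizations. The parameter space is partitioned into contiguous
    blocks so candidates can be evaluated by independent parallel workers
    with results invariant to the worker count. Reads and writes an
    SMBioNet-style four-section model format (VAR/REG/PARA/CTL), exports
    state graphs as DOT or GraphML, and ships the textbook Pseudomonas
    aeruginosa mucus-production network plus generators for seeded random
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    parallel,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
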