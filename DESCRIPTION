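Package: plasmidstab
Title: Stochastic Models of Low-Copy Plasmid Segregation, Stability and
    Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact per-generation models of low-copy plasmid inheritance in
    growing bacterial populations.  Plasmid variants are characterized by a
    monomerization deficiency, an active-partition efficiency and a
    post-segregational-killing efficiency; the package composes the full
    cell life cycle (Polya-urn replication, binomial multimer depletion,
    random or pairwise-balanced assortment, toxin-antitoxin killing) into
    an expected-offspring matrix over all cell states, propagates cell-type
    proportions deterministically over generations, and derives persistence
    curves, plasmid half-lives, asymptotic segregation rates and
    head-to-head competition trajectories.  A seeded agent-level
    Monte-Carlo simulator provides an independent oracle, and serial-
    transfer persistence data can be generated synthetically and used to
    calibrate the variant parameters by binomial maximum likelihood with
    bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
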