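Package: totemsim
Title: Seeded Simulator of Cumulative Cultural Evolution on Combinatorial
    Technology Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An agent-based simulator of cumulative cultural evolution in
    the style of combinatorial crafting games. Generates nested technology
    trees (base resources, intermediate tools, high-value logs), runs
    random-search bot agents with a unique-attempt budget, with or without
    social learning, under several population structures (isolated agents,
    fully connected groups, and metapopulations with rotating reciprocal
    ties), and computes replicated experiment summaries. All randomness is
    seeded and every run is exactly reproducible.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
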