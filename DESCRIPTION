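Package: bridesnet
Title: Path-Type Classification in Evolving Similarity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes how an undirected (optionally weighted) network
    evolves when new nodes are added. Every pair of original nodes is
    classified as a Breakthrough, Roadblock, Impasse, Detour, Equal path or
    Shortcut by comparing the shortest-path distance in the original network
    with the length of the shortest simple path in the augmented network that
    is forced to traverse at least one added node. Implements the original
    concatenation heuristic, two variants based on Yen's k-shortest loopless
    paths, an exhaustive-concatenation variant, and two exact reference
    classifiers (brute-force depth-first search and a polynomial minimum-cost
    flow formulation) used as ground truth. Includes a random-graph benchmark
    comparing heuristic labels against the exact reference under Erdos-Renyi,
    Barabasi-Albert and Watts-Strogatz models, tools for reading and
    summarising tab-separated edge lists, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    graphics,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
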