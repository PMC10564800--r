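Package: phyclus
Title: Rooted Phylogenetic Networks and Their Clustering Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Data structures and algorithms for rooted phylogenetic networks
    and the set systems of hardwired clusters they induce. Provides structural
    classification of networks (phylogenetic, separated, binary, tree-child,
    normal, tree-based, galled, level-k), predicates on clustering systems
    (hierarchy, weak hierarchy, closure under intersection, property (L),
    (N3O), (2-Inc)), least-common-ancestor machinery for DAGs, the canonical
    constructions linking networks and cluster systems (Hasse/regular network,
    cluster network, least-resolved level-1 network), graph rewrites
    (arc expansion and contraction, shortcut removal, regularization), and a
    polynomial-time compatibility test that decides whether a clustering
    system is displayed by a (separated, phylogenetic) level-1 network and
    constructs one when it exists. Includes seeded generators for random
    level-1 networks, brute-force oracles, and readers/writers for extended
    Newick and tab-separated edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
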