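---
title: "Networks, clusters, and the level-1 calculus: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Networks, clusters, and the level-1 calculus: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyclus)
```

## The model

A *network* here is the most general object the field admits: a directed
acyclic graph with a single root from which every vertex is reachable. The
taxa `X` are the vertices of outdegree 0; a vertex with more than one parent
is a *hybrid*. Nothing else is assumed — inner vertices may have outdegree
1, hybrids may have any out- or indegree, leaves may themselves be hybrids.
All the familiar restrictions (phylogenetic, separated, binary, tree-child,
…) are explicit predicates (`structural_flags()`, `is_tree_child()`, …),
not baked into the data model. This permissive base class matters: regular
networks, which are central to the cluster calculus, are never separated
once they contain a hybrid, so any fixed normalisation would exclude part of
the theory.

Every vertex `v` defines the hardwired cluster `C(v)` of taxa below it; the
set of all clusters is the clustering system `C_N`, and the multiset `M_N`
counts each cluster once per vertex displaying it. The package's purpose is
the two-way traffic between properties of `N` and properties of `C_N`:

* `C_N` is always a clustering system (contains `X` and all singletons).
* The Hasse diagram of any clustering system, with singletons relabelled by
  their taxon, is the unique **regular** network displaying exactly those
  clusters (`hasse()`); it is shortcut-free, satisfies path–cluster
  comparability, and has no outdegree-1 vertex.
* **Semi-regular** networks (shortcut-free + (PCC)) are encoded by their
  cluster multisets; the witness bijection `phi_pcc()` simply aligns, for
  each cluster, the two chains of vertices displaying it.
* The **cluster network** (`cluster_network_of()`) — the regular network
  with every hybrid expanded — is the unique semi-regular, separated,
  phylogenetic network for a given system.
* A system is displayed by some **level-1** network iff it is closed under
  non-empty intersections and satisfies **property (L)**: each cluster meets
  all clusters it overlaps in one and the same set. Galled trees add
  (N3O) — no three pairwise overlapping clusters — and binary level-1
  networks add (2-Inc): at most two cover-parents and cover-children per
  cluster in the inclusion order.

## The compatibility test

`check_l1_compatibility()` answers the weaker and practically more useful
question: is there a (separated, phylogenetic) level-1 network whose
clusters *include* the given ones? The implemented route:

1. test property (L) directly, grouping each cluster's overlap partners and
   comparing the intersections;
2. if (L) holds, build the intersection closure `I(C)`. Under (L) the
   closure of any subfamily equals a pairwise intersection, so iterating
   pairwise intersections to a fixpoint is exact (and terminates after one
   sweep adds nothing);
3. return the cluster network of `I(C)`; its clustering system is exactly
   `I(C)`, it is level-1, separated, and phylogenetic.

Compatibility is therefore *equivalent* to property (L) — closedness is
obtained for free through the closure, which never destroys (L). The binary
variant additionally requires every hybrid of the closure's Hasse diagram to
have indegree 2, then refines multifurcations: hybrids of outdegree other
than one are expanded, and each remaining vertex of outdegree above two is
replaced by a caterpillar whose items are its non-block children plus one
slot per cycle block rooted there (the block's two cycle children re-attach
beneath their slot, so cycles are never broken). Caterpillar items are
chained by the smallest taxon label below them; output is deterministic.

The asymptotic cost of this reconstruction is not guaranteed to match the
best published bound for the problem; correctness, not the constant or the
exponent, is the contract, and the implementation is quadratic-ish in the
number of clusters at the instance sizes the package targets (tens of taxa).

## LCA machinery

`lca_set()` intersects per-leaf ancestor sets read off a single reachability
matrix and keeps the minimal elements, avoiding per-query traversals.
`is_lca_network()` prefers the structural shortcut — under (PCC),
lca-uniqueness for all leaf subsets is equivalent to closedness of `C_N` —
and falls back to exhaustive enumeration of the `2^|X| - 1` subsets,
accepted up to `|X| = 12` (the attribute `route` reports which path
decided). The strong variant composes the lca-network decision with the
weak-hierarchy test of `C_N`; a brute-force pair-witness check
(`phyclus:::strong_lca_brute`) guards that equivalence in the test suite for
small `|X|`.

## Tree-based networks via matching

A network is tree-based when some choice of one in-arc per non-root vertex
leaves no inner vertex childless. Any inner vertex with a tree child keeps
that arc automatically, so only the *omnians* — inner vertices all of whose
children are hybrid — are at risk; the decision reduces to a bipartite
matching between omnians and their children that saturates the omnians.
The spanning-tree formulation is taken as the definition (the package's
general setting allows attachment points of indegree above one), and the
matching reduction is validated against a brute-force enumeration of all
parent-choice functions rather than re-proved; the suites run that
comparison on hundreds of generated instances with at most ten non-root
vertices, and the two have never disagreed.

## The synthetic generator

`gen_random_level1()` defines the study conditions for all randomised
suites. It grows a random phylogenetic tree by uniform attachment over a
deliberately small pool of inner vertices (at most `n/3`), which produces
the multifurcations that cycle insertion needs, then converts `n_blocks`
inner vertices into undirected cycles: the vertex becomes the cycle
maximum, a fresh hybrid of indegree 2 its terminal vertex, and each interior
cycle vertex adopts one former subtree so that every vertex stays
phylogenetic. Only children reached over cut arcs may be moved into a new
cycle — re-routing an existing cycle arc would merge two blocks and raise
the level. Defaults: `max_block_size = 5`, cycles of length at least 4 when
shortcuts are disallowed (a 3-cycle forces the chord to be a shortcut), and
`n_blocks` scaling as roughly one block per three taxa in the test helper.
Identical configuration and seed give bit-identical networks; the seed is
saved and restored around generation.

What the generator emulates: phylogenetic, separated, tree-child,
shortcut-free level-1 networks with quasi-binary blocks — the class at the
centre of the characterisation theorems — plus optional binary refinement
and optional shortcut chords. What it does not emulate: hybrids of indegree
above two, non-phylogenetic chains, multiple hybrids per block, or any
likelihood-based notion of realism (branch lengths, clock models, taxon
sampling). Passing suites therefore certify the combinatorial calculus on
exactly this class, not the behaviour of inference tools on empirical data;
negative and out-of-class cases enter through the fixtures (two hybrids per
block, shortcuts, the complete-bipartite level-`k` family, printed
counterexample systems) and through mutation (`break_property_l()`).

## Numerical and design choices

* **Vertex identity.** Ids are opaque strings. Rewrites preserve surviving
  ids exactly: expansion adds `<v>__exp<k>`, contraction deletes the upper
  vertex of the arc, caterpillar refinement adds `<v>__cat<k>` and
  `<v>__slot<k>`. Parallel arcs are rejected at build time; contraction
  silently drops would-be duplicates, matching the re-attachment semantics
  of the rewrite.
* **Blocks** come from biconnected components of the underlying undirected
  graph; the single-vertex network is its own trivial block. Each block
  carries its unique maximal vertex and its minimal (terminal) vertices,
  computed against the global ancestor order.
* **Determinism.** All tie-breaks are lexicographic on vertex ids or taxon
  labels: the matching witness, the eNewick primary parent of a hybrid,
  caterpillar chaining, and cluster ordering (size, then key). Clusters are
  canonical sorted label vectors, so set-of-sets equality and multiset
  counting are exact.
* **Isomorphism** uses joint colour refinement (seeded with leaf labels and
  degrees) plus backtracking. Instances in this package are small (at most
  a few dozen vertices), so the worst case is acceptable; `phi_pcc()` is the
  preferred witness whenever multisets are known to agree.
* **Regularization order.** Shortcuts are removed before outdegree-1
  contractions, re-scanning after each step; the result is order-independent
  for (PCC) networks, and the test suite replays an inverted order to
  confirm. For level-1 inputs the same rewrite loop is sound without the
  (PCC) precondition (`least_resolved_level1()` uses `check = FALSE`).
* **Degenerate inputs.** The one-vertex network is phylogenetic and
  separated by convention, has level 0, and its leaf set is its only
  vertex. `cl(∅) = ∅` for more than one taxon. `Top(X) = X`.
* **Pre-pyramidality** is decided through (N3O) whenever (L) holds; without
  (L) a backtracking search over total orders runs for at most ten taxa,
  pruning prefixes in which a partially placed cluster is not a contiguous
  suffix.
* **Enumeration.** `enumerate_small_networks()` generates phylogenetic
  quasi-binary level-1 networks recursively: a component root is a leaf, a
  tree vertex over a set partition, or a cycle maximum with two chains
  meeting in an indegree-2 hybrid; an empty second chain realises the
  shortcut chord. In this class these are the only shapes — a block maximum
  has outdegree exactly 2, so blocks never share maxima, and interior cycle
  vertices cannot head further blocks. Reflection and ordering duplicates
  are removed by invariant bucketing plus pairwise isomorphism. The
  enumeration is restricted to this class; uniqueness statements about the
  broader separated level-1 class are exercised instead by comparing
  independently generated witnesses against `cluster_network_of()`.

## Problem sizes

The suites run at fixed sizes chosen to finish comfortably on one CPU:
4–10 taxa per generated network, 200 seeded systems for the multiplicity
law, 500 networks for the characterisation round trips, 300 rebuilt copies
for `phi_pcc`, exhaustive enumeration up to four taxa (vertex cap 9 in the
multiset-encoding check), 500 instances for the tree-based oracle, all
`2^|X| - 1` LCA queries for up to six taxa, and 1000 systems (half mutated
to break (L)) for the compatibility test. The acceptance script replays the
same computations from a single command-line seed.

## Known limitations

* Level-`k` compatibility for `k >= 2` is out of scope (and open in
  general); the package only certifies the level of a given network.
* The compatibility witness is the canonical separated one; the package
  does not enumerate all witnesses, nor minimise hybrid numbers.
* `is_lca_network()` without (PCC) is exponential in `|X|` and refuses
  beyond 12 taxa.
* The uniform-attachment tree shape is not uniform over tree topologies;
  it is adequate for property testing, not for simulation studies that need
  a calibrated null model.
* Softwired clusters are deliberately not modelled.
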