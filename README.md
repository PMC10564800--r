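# phyclus

Rooted phylogenetic networks and their clustering systems, in R.

When evolution involves hybridization, recombination or horizontal transfer,
the history of a set of taxa *X* is a rooted directed acyclic graph rather
than a tree. Every vertex *v* of such a network *N* still defines a
*hardwired cluster* `C(v)` — the set of taxa reachable from *v* — and the
collection of all these clusters, the *clustering system* `C_N`, is the part
of the network that is realistically estimable from data. `phyclus`
implements the calculus that relates the two sides:

* **Networks.** A general rooted-DAG data model with the structural
  predicates of the field: phylogenetic, separated, binary, quasi-binary,
  conventional, shortcut-free, tree-child, normal, tree-based (via a
  bipartite matching over the omnians), galled tree, and level-*k*
  (per-block hybrid counts).
* **Clustering systems.** Hierarchies, weak hierarchies, closure under
  intersection, the closure operator `cl(A)`, property (L) (all overlap
  intersections of a cluster coincide), (N3O), paired hierarchies, (2-Inc),
  pre-binary/binary systems, and pre-pyramidality.
* **Canonical constructions.** The Hasse diagram `H[C]` as the unique
  *regular* network of a system; the *cluster network* (regular network with
  hybrids expanded) as the unique semi-regular, separated, phylogenetic
  witness; regularization of any (PCC) network by shortcut removal and
  contraction; the positional map `phi_PCC` that proves semi-regular
  networks are encoded by their cluster *multisets*.
* **LCA machinery.** Minimal common ancestor sets in DAGs, the cluster-lca
  property (CL), lca-networks (unique `lca(A)` for every `A ⊆ X`,
  equivalent to closedness of `C_N` under (PCC)) and strong lca-networks
  (equivalent to closed weak hierarchies).
* **Level-1 theory.** A clustering system is displayed exactly by a level-1
  network iff it is closed and satisfies (L); adding (N3O) characterises
  galled trees, adding (2-Inc) binary level-1 networks. The polynomial-time
  compatibility test `check_l1_compatibility()` decides whether *some*
  (separated, phylogenetic) level-1 network displays all clusters of a
  system — equivalent to property (L) alone — and builds one from the
  intersection closure; `binary_l1_compatible()` adds caterpillar
  refinement to produce a binary witness.

Everything is plain base R on top of `igraph` (biconnected components,
reachability, matchings) and `jsonlite`.

## A worked example

Three taxa, with conflicting groupings `{x,y}` and `{y,z}` — impossible in
a tree, routine for a level-1 network:

```r
library(phyclus)

CS <- clustsys(list("x", "y", "z", c("x","y"), c("y","z"), c("x","y","z")))
unlist(cs_flags(CS))
#>        hierarchy       pre_binary           binary   weak_hierarchy
#>            FALSE             TRUE             TRUE             TRUE
#>       property_L              n3o paired_hierarchy          two_inc
#>             TRUE             TRUE             TRUE             TRUE

r <- check_l1_compatibility(CS)
r$compatible
#> [1] TRUE
r$n_clusters_added        # the system was already intersection-closed
#> [1] 0
write_enewick(r$network)
#> [1] "((x,(y)#H1),(#H1,z));"
```

The witness is the unique separated phylogenetic shortcut-free level-1
network for this system — a single 4-cycle whose hybrid is the ancestor of
`y`:

```r
unlist(structural_flags(r$network))
#> phylogenetic separated binary quasi_binary conventional shortcut_free
#>         TRUE      TRUE   TRUE         TRUE         TRUE          TRUE
network_level(r$network)
#> [1] 1

M <- cluster_multiset(r$network)
data.frame(cluster = sapply(M$clusters, paste, collapse = ","), mult = M$count)
#>   cluster mult
#> 1       x    1
#> 2       y    2   # the hybrid and the leaf below it
#> 3       z    1
#> 4     x,y    1
#> 5     y,z    1
#> 6   x,y,z    1

lca_set(r$network, c("x", "z"))$lca_set   # unique: level-1 nets are lca-networks
#> [1] "{x,y,z}"
```

Multiplicity 2 for `{y}` is no accident: in any semi-regular phylogenetic
network each cluster appears at most twice, and twice only on the two ends
of an arc.

## Command line

A thin wrapper lives in `inst/cli/phyclus.R`:

```sh
Rscript inst/cli/phyclus.R gen level1 --n 8 --blocks 2 --seed 42 -o net.enwk
Rscript inst/cli/phyclus.R classify net.enwk
Rscript inst/cli/phyclus.R l1-compat cs.json --binary -o witness.enwk
```

`l1-compat` prints a JSON report and exits 0/1 with the decision.

## Further reading

The methods vignette (`vignettes/clustering-systems.Rmd`) explains the
model, the characterisations the package implements, what the synthetic
generator does and does not emulate, and the numerical/design choices.
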