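# Least common ancestors in rooted DAGs.  Ancestor sets per leaf are taken
# from the cached reachability matrix and intersected, so no per-query graph
# traversal is needed.

# vertices that are common ancestors of a label set A
common_ancestors <- function(N, A, reach = nw_reach(N)) {
  vids <- N$leaves[match(A, unname(N$labels[N$leaves]))]
  if (anyNA(vids)) phyclus_stop("UnknownLeaf", "unknown leaf label in query")
  anc <- reach[, vids, drop = FALSE]
  N$vertices[rowSums(anc) == length(vids)]
}

minimal_among <- function(N, verts, reach = nw_reach(N)) {
  verts[vapply(verts, function(v)
    !any(reach[v, setdiff(verts, v)]), logical(1))]
}

#' Least common ancestors of a leaf set
#'
#' Returns the set of minimal common ancestors of a non-empty set of leaf
#' labels.  The root is an ancestor of everything, so the set is never
#' empty; it is a singleton exactly when the LCA is unique.
#'
#' @param N a `phynet`
#' @param A non-empty character vector of leaf labels
#' @return list with `query`, `lca_set` (sorted vertex ids) and `unique`
#' @export
lca_set <- function(N, A) {
  A <- unique(as.character(A))
  if (length(A) == 0L) phyclus_stop("EmptyQuery", "query leaf set is empty")
  reach <- nw_reach(N)
  ca <- common_ancestors(N, A, reach)
  mins <- sort(minimal_among(N, ca, reach))
  list(query = sort(A), lca_set = mins, unique = length(mins) == 1L)
}

#' Cluster-lca property (CL)
#'
#' A network has property (CL) if, for every vertex `v`, the cluster of `v`
#' has a unique least common ancestor.  When this holds, that LCA lies below
#' `v` and displays the same cluster.
#'
#' @param N a `phynet`
#' @return logical scalar
#' @export
has_cl <- function(N) {
  reach <- nw_reach(N)
  cls <- nw_clusters(N, reach)
  seen <- character(0)
  for (v in N$vertices) {
    k <- cl_key(cls[[v]])
    if (k %in% seen) next
    seen <- c(seen, k)
    ca <- common_ancestors(N, cls[[v]], reach)
    if (length(minimal_among(N, ca, reach)) != 1L) return(FALSE)
  }
  TRUE
}

#' lca-networks and strong lca-networks
#'
#' A network is an lca-network if every non-empty subset of leaves has a
#' unique least common ancestor; it is a strong lca-network if, in addition,
#' the LCA of every leaf set is attained by one of its leaf pairs.
#'
#' When the network satisfies path-cluster comparability, being an
#' lca-network is equivalent to the clustering system being closed, and the
#' strong variant to the clustering system being a (closed) weak hierarchy;
#' these shortcuts are used whenever available.  Otherwise the decision is
#' exhaustive over all non-empty leaf subsets, permitted only for small
#' ground sets.
#'
#' @param N a `phynet`
#' @param max_exhaustive largest leaf set for which exhaustive enumeration of
#'   subsets is attempted when the shortcut does not apply (default 12)
#' @return logical scalar, with attribute `route` recording which decision
#'   path was taken (`"pcc"` or `"exhaustive"`)
#' @export
is_lca_network <- function(N, max_exhaustive = 12L) {
  if (is_pcc(N)) {
    return(structure(is_closed(clustering_system(N)), route = "pcc"))
  }
  X <- leaf_set(N)
  if (length(X) > max_exhaustive)
    phyclus_stop("GroundSetTooLarge",
                 "leaf set too large for exhaustive lca enumeration without (PCC)")
  structure(all_subsets_unique_lca(N), route = "exhaustive")
}

all_subsets_unique_lca <- function(N) {
  X <- leaf_set(N)
  reach <- nw_reach(N)
  lv <- N$leaves[match(X, unname(N$labels[N$leaves]))]
  anc <- reach[, lv, drop = FALSE]  # vertices x leaves
  n <- length(X)
  for (mask in seq_len(2^n - 1L)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))
    ca <- N$vertices[rowSums(anc[, sel, drop = FALSE]) == sum(sel)]
    if (length(minimal_among(N, ca, reach)) != 1L) return(FALSE)
  }
  TRUE
}

#' @rdname is_lca_network
#' @export
is_strong_lca_network <- function(N, max_exhaustive = 12L) {
  if (!isTRUE(as.logical(is_lca_network(N, max_exhaustive)))) return(FALSE)
  is_weak_hierarchy(clustering_system(N))
}

# brute-force pair-witness check of the strong lca property, for tests
strong_lca_brute <- function(N) {
  X <- leaf_set(N)
  if (!isTRUE(as.logical(is_lca_network(N)))) return(FALSE)
  n <- length(X)
  for (mask in seq_len(2^n - 1L)) {
    A <- X[as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)))]
    la <- lca_set(N, A)$lca_set
    pairs_ok <- FALSE
    for (i in seq_along(A)) {
      for (j in i:length(A)) {
        if (identical(lca_set(N, c(A[i], A[j]))$lca_set, la)) {
          pairs_ok <- TRUE; break
        }
      }
      if (pairs_ok) break
    }
    if (!pairs_ok) return(FALSE)
  }
  TRUE
}

#' Path-cluster comparability (PCC)
#'
#' Two vertices are comparable in the ancestor order exactly when their
#' clusters are nested.
#'
#' @param N a `phynet`
#' @return logical scalar
#' @export
is_pcc <- function(N) {
  reach <- nw_reach(N)
  cls <- nw_clusters(N, reach)
  V <- N$vertices
  n <- length(V)
  if (n < 2L) return(TRUE)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    u <- V[i]; v <- V[j]
    comparable <- reach[u, v] || reach[v, u]
    nested <- all(cls[[u]] %in% cls[[v]]) || all(cls[[v]] %in% cls[[u]])
    if (comparable != nested) return(FALSE)
  }
  TRUE
}

#' Regularity ladder of a network
#'
#' Classifies a network along the regularity hierarchy: semi-regular
#' (shortcut-free and (PCC)), regular (semi-regular with no outdegree-1
#' vertex; equivalently isomorphic to the Hasse diagram of its clustering
#' system), and cluster network (semi-regular, separated and phylogenetic).
#' Since regularity together with (PCC) characterises the least-resolved
#' networks, `least_resolved` mirrors the regular flag.
#'
#' @param N a `phynet`
#' @return named list of logicals `semi_regular`, `regular`,
#'   `cluster_network`, `least_resolved_candidate`
#' @export
classify_regularity <- function(N) {
  fl <- structural_flags(N)
  pcc <- is_pcc(N)
  semi_regular <- fl$shortcut_free && pcc
  regular <- semi_regular && !any(nw_outdeg(N) == 1L)
  cluster_network <- semi_regular && fl$separated && fl$phylogenetic
  list(semi_regular = semi_regular, regular = regular,
       cluster_network = cluster_network,
       least_resolved_candidate = regular)
}

#' Equal-cluster path of a vertex
#'
#' In a semi-regular network the vertices sharing the cluster of `u` lie
#' consecutively along an induced directed path; `q_path` returns them in
#' descending ancestor order (top of the chain first).
#'
#' @param N a semi-regular `phynet`
#' @param u vertex id
#' @return character vector of vertex ids
#' @export
q_path <- function(N, u) {
  if (!(u %in% N$vertices)) phyclus_stop("UnknownVertex", paste("unknown vertex", u))
  if (!classify_regularity(N)$semi_regular)
    phyclus_stop("NotSemiRegular", "q_path requires a semi-regular network")
  reach <- nw_reach(N)
  cls <- nw_clusters(N, reach)
  k <- cl_key(cls[[u]])
  Q <- N$vertices[vapply(N$vertices, function(v) cl_key(cls[[v]]) == k, logical(1))]
  # sort descending: ancestors first
  ord <- order(vapply(Q, function(v) sum(reach[Q, v]), integer(1)))
  Q <- Q[ord]
  # assert the chain is an induced directed path
  if (length(Q) > 1L) {
    for (i in seq_len(length(Q) - 1L)) {
      if (!nw_has_arc(N, Q[i], Q[i + 1L]))
        phyclus_stop("InternalInvariant", "equal-cluster set is not a path")
    }
  }
  Q
}
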