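#' @keywords internal
"_PACKAGE"

#' @importFrom igraph graph_from_edgelist make_empty_graph V distances
#'   as_undirected biconnected_components max_bipartite_match add_vertices
#'   is_dag subcomponent
NULL

# Error helper: every user-facing failure carries a condition class so that
# callers (and tests) can dispatch on the kind of violation.
phyclus_stop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "phyclus_error", "error", "condition")))
}

#' Build a rooted phylogenetic network
#'
#' A network is a rooted directed acyclic graph: it has exactly one vertex of
#' indegree 0 (the root), every vertex is reachable from the root, and the
#' vertices of outdegree 0 (the leaves) carry the taxon labels.  No further
#' structural restriction is imposed: inner vertices may have outdegree 1,
#' hybrid vertices (indegree greater than 1) may have any outdegree, and
#' leaves may themselves be hybrids.
#'
#' @param arcs two-column character matrix (or data frame) of arcs, each row a
#'   `parent, child` pair of vertex ids.  Vertex ids are opaque strings.
#' @param leaf_labels optional named character vector mapping leaf vertex ids
#'   to taxon labels; defaults to the identity on the leaf ids.
#' @param isolated_root for the degenerate single-vertex network, the id of
#'   the sole vertex; `arcs` must then be empty.
#'
#' @return An object of class `phynet` with components `vertices`, `edges`
#'   (two-column character matrix), `root`, `leaves` and `labels`.
#'
#' @details Validation rejects multiple roots (`MultipleRoots`), directed
#'   cycles (`CyclicGraph`), vertices unreachable from the root
#'   (`UnreachableVertex`), self-loops and parallel arcs, and label maps that
#'   do not biject onto the leaf set (`LeafLabelMismatch`).
#'
#' @examples
#' N <- build_network(rbind(c("r", "a"), c("r", "3"), c("a", "1"), c("a", "2")))
#' leaf_set(N)
#' @export
build_network <- function(arcs, leaf_labels = NULL, isolated_root = NULL) {
  if (!is.null(isolated_root)) {
    if (!(is.null(arcs) || NROW(arcs) == 0L))
      phyclus_stop("InvalidInput", "isolated_root given together with arcs")
    v <- as.character(isolated_root)
    labels <- if (is.null(leaf_labels)) stats::setNames(v, v) else leaf_labels
    if (!identical(sort(names(labels)), v))
      phyclus_stop("LeafLabelMismatch", "labels must cover exactly the single vertex")
    return(new_phynet(v, matrix(character(0), 0, 2), v, labels))
  }
  if (is.data.frame(arcs)) arcs <- as.matrix(arcs)
  if (is.null(dim(arcs)) && length(arcs) == 2L) arcs <- matrix(arcs, 1L, 2L)
  if (NROW(arcs) == 0L)
    phyclus_stop("InvalidInput", "no arcs given; use isolated_root for a single vertex")
  arcs <- matrix(as.character(arcs), ncol = 2L,
                 dimnames = list(NULL, c("parent", "child")))
  if (any(arcs[, 1L] == arcs[, 2L]))
    phyclus_stop("CyclicGraph", "self-loops are not allowed")
  key <- paste(arcs[, 1L], arcs[, 2L], sep = "\r")
  if (anyDuplicated(key))
    phyclus_stop("InvalidInput", "parallel arcs are not allowed")
  vertices <- unique(c(arcs[, 1L], arcs[, 2L]))
  indeg <- table(factor(arcs[, 2L], levels = vertices))
  roots <- vertices[indeg == 0L]
  if (length(roots) == 0L)
    phyclus_stop("CyclicGraph", "graph has no vertex of indegree 0")
  if (length(roots) > 1L)
    phyclus_stop("MultipleRoots",
                 paste("multiple indegree-0 vertices:", paste(roots, collapse = ", ")))
  g <- igraph::graph_from_edgelist(arcs, directed = TRUE)
  if (!igraph::is_dag(g))
    phyclus_stop("CyclicGraph", "graph contains a directed cycle")
  reach <- igraph::subcomponent(g, roots, mode = "out")$name
  if (length(reach) < length(vertices)) {
    miss <- setdiff(vertices, reach)
    phyclus_stop("UnreachableVertex",
                 paste("unreachable from root:", paste(miss, collapse = ", ")))
  }
  outdeg <- table(factor(arcs[, 1L], levels = vertices))
  leaves <- vertices[outdeg == 0L]
  if (is.null(leaf_labels)) {
    labels <- stats::setNames(leaves, leaves)
  } else {
    labels <- leaf_labels
    if (!setequal(names(labels), leaves) || anyDuplicated(unname(labels)))
      phyclus_stop("LeafLabelMismatch",
                   "leaf_labels must be a bijection from the outdegree-0 vertices")
    labels <- labels[leaves]
  }
  new_phynet(vertices, arcs, roots, labels)
}

new_phynet <- function(vertices, edges, root, labels) {
  structure(list(vertices = vertices,
                 edges = edges,
                 root = root,
                 leaves = sort(names(labels)),
                 labels = labels[sort(names(labels))]),
            class = "phynet")
}

#' @export
print.phynet <- function(x, ...) {
  cat(sprintf("<phynet: %d vertices, %d arcs, %d leaves; root = %s>\n",
              length(x$vertices), nrow(x$edges), length(x$leaves), x$root))
  invisible(x)
}

#' Leaf label set of a network
#' @param N a `phynet` object
#' @return character vector of taxon labels (sorted)
#' @export
leaf_set <- function(N) sort(unname(N$labels))

# ---- internal accessors ----------------------------------------------------

nw_igraph <- function(N) {
  if (nrow(N$edges) == 0L) {
    g <- igraph::make_empty_graph(directed = TRUE)
    g <- igraph::add_vertices(g, 1L, name = N$vertices)
    return(g)
  }
  igraph::graph_from_edgelist(N$edges, directed = TRUE)
}

nw_outdeg <- function(N) {
  tab <- table(factor(N$edges[, 1L], levels = N$vertices))
  stats::setNames(as.integer(tab), N$vertices)
}

nw_indeg <- function(N) {
  tab <- table(factor(N$edges[, 2L], levels = N$vertices))
  stats::setNames(as.integer(tab), N$vertices)
}

nw_children <- function(N, v) N$edges[N$edges[, 1L] == v, 2L]
nw_parents  <- function(N, v) N$edges[N$edges[, 2L] == v, 1L]

# Reachability matrix R[i, j] == TRUE iff there is a directed path from
# vertex i to vertex j (i.e. j descends from i); reflexive by convention.
nw_reach <- function(N) {
  g <- nw_igraph(N)
  d <- igraph::distances(g, mode = "out", algorithm = "unweighted")
  r <- is.finite(d)
  nm <- igraph::V(g)$name
  dimnames(r) <- list(nm, nm)
  r[N$vertices, N$vertices, drop = FALSE]
}

nw_has_arc <- function(N, u, w) any(N$edges[, 1L] == u & N$edges[, 2L] == w)

nw_hybrids <- function(N) names(which(nw_indeg(N) > 1L))

#' Ancestor relation in a network
#'
#' `descends(N, u, v)` is `TRUE` iff `u` lies below `v` in the ancestor
#' partial order, i.e. there is a (possibly empty) directed path from `v`
#' to `u`.  The relation is reflexive.
#'
#' @param N a `phynet`
#' @param u,v vertex ids
#' @return logical scalar
#' @export
descends <- function(N, u, v) {
  if (!(u %in% N$vertices) || !(v %in% N$vertices))
    phyclus_stop("UnknownVertex", "u and v must be vertices of N")
  nw_reach(N)[v, u]
}

# ---- blocks ----------------------------------------------------------------

#' Blocks (maximal biconnected subgraphs) of a network
#'
#' The blocks of the underlying undirected graph of `N`.  Every arc lies in
#' exactly one block; a block is non-trivial iff it contains an undirected
#' cycle (equivalently, at least three vertices).  Each block is returned
#' with its unique maximal vertex with respect to the ancestor order, and
#' with its minimal (terminal) vertices.  A single-vertex network is its own
#' trivial block.
#'
#' @param N a `phynet`
#' @return list of blocks; each block is a list with components `vertices`,
#'   `arcs` (two-column matrix), `max_vertex`, `terminal_vertices` and
#'   `nontrivial`.
#' @export
blocks <- function(N) {
  if (nrow(N$edges) == 0L) {
    return(list(list(vertices = N$vertices,
                     arcs = matrix(character(0), 0, 2),
                     max_vertex = N$root,
                     terminal_vertices = N$root,
                     nontrivial = FALSE)))
  }
  g <- nw_igraph(N)
  ug <- igraph::as_undirected(g, mode = "each")
  bc <- igraph::biconnected_components(ug)
  reach <- nw_reach(N)
  lapply(bc$components, function(vs) {
    verts <- sort(vs$name)
    sub <- N$edges[N$edges[, 1L] %in% verts & N$edges[, 2L] %in% verts, ,
                   drop = FALSE]
    rsub <- reach[verts, verts, drop = FALSE]
    maxv <- verts[vapply(verts, function(v)
      !any(rsub[setdiff(verts, v), v]), logical(1))]
    minv <- verts[vapply(verts, function(v)
      !any(rsub[v, setdiff(verts, v)]), logical(1))]
    list(vertices = verts,
         arcs = sub,
         max_vertex = maxv,
         terminal_vertices = sort(minv),
         nontrivial = length(verts) >= 3L)
  })
}

#' Shortcut arcs
#'
#' An arc `(u, w)` is a shortcut if the network contains a directed path from
#' `u` to `w` avoiding the arc itself, i.e. some other child of `u` is a
#' strict ancestor of `w`.
#'
#' @param N a `phynet`
#' @param arc length-2 character vector `c(u, w)`
#' @return `is_shortcut` a logical scalar; `shortcuts` a two-column matrix of
#'   all shortcut arcs (zero rows when none).
#' @export
is_shortcut <- function(N, arc) {
  u <- arc[[1L]]; w <- arc[[2L]]
  if (!nw_has_arc(N, u, w))
    phyclus_stop("UnknownArc", sprintf("(%s, %s) is not an arc of N", u, w))
  reach <- nw_reach(N)
  other <- setdiff(nw_children(N, u), w)
  length(other) > 0L && any(reach[other, w])
}

#' @rdname is_shortcut
#' @export
shortcuts <- function(N) {
  if (nrow(N$edges) == 0L) return(N$edges)
  reach <- nw_reach(N)
  keep <- vapply(seq_len(nrow(N$edges)), function(i) {
    u <- N$edges[i, 1L]; w <- N$edges[i, 2L]
    other <- setdiff(nw_children(N, u), w)
    length(other) > 0L && any(reach[other, w])
  }, logical(1))
  N$edges[keep, , drop = FALSE]
}

#' Level of a network
#'
#' The level is the maximum, over all blocks `B`, of the number of hybrid
#' vertices in `B` distinct from the block maximum.  Trees have level 0.
#'
#' @param N a `phynet`
#' @return non-negative integer
#' @export
network_level <- function(N) {
  hyb <- nw_hybrids(N)
  if (length(hyb) == 0L) return(0L)
  bl <- blocks(N)
  max(vapply(bl, function(b)
    length(setdiff(intersect(b$vertices, hyb), b$max_vertex)), integer(1)))
}

#' Vertex roles
#'
#' Classifies every vertex as `leaf` (outdegree 0), `hybrid` (indegree > 1)
#' or `tree` (indegree at most 1); a leaf is additionally tree or hybrid,
#' recorded in `leaf_kind`.
#'
#' @param N a `phynet`
#' @return data frame with columns `vertex`, `indegree`, `outdegree`, `role`,
#'   `leaf_kind`
#' @export
vertex_roles <- function(N) {
  ind <- nw_indeg(N); outd <- nw_outdeg(N)
  role <- ifelse(outd == 0L, "leaf", ifelse(ind > 1L, "hybrid", "tree"))
  data.frame(vertex = N$vertices,
             indegree = unname(ind), outdegree = unname(outd),
             role = unname(role),
             leaf_kind = ifelse(outd == 0L,
                                ifelse(ind > 1L, "hybrid", "tree"), NA_character_),
             stringsAsFactors = FALSE)
}

#' Structural flags of a network
#'
#' Evaluates the six basic structural predicates:
#' \describe{
#'   \item{phylogenetic}{no vertex with outdegree 1 and indegree at most 1}
#'   \item{separated}{every hybrid vertex has outdegree 1}
#'   \item{binary}{tree vertices are leaves or have outdegree 2; hybrids have
#'     indegree 2 and outdegree 1}
#'   \item{quasi_binary}{hybrids have indegree 2 and outdegree 1, and the
#'     maximum of every non-trivial block has outdegree 2}
#'   \item{conventional}{leaves have indegree at most 1 and every hybrid lies
#'     in exactly one non-trivial block}
#'   \item{shortcut_free}{no shortcut arcs}
#' }
#'
#' @param N a `phynet`
#' @return named logical vector (as a list) with the six flags
#' @export
structural_flags <- function(N) {
  ind <- nw_indeg(N); outd <- nw_outdeg(N)
  hyb <- names(which(ind > 1L))
  phylogenetic <- !any(outd == 1L & ind <= 1L)
  separated <- length(hyb) == 0L || all(outd[hyb] == 1L)
  treev <- names(which(ind <= 1L))
  binary <- all(outd[treev] %in% c(0L, 2L)) &&
    (length(hyb) == 0L || all(ind[hyb] == 2L & outd[hyb] == 1L))
  bl <- blocks(N)
  nontriv <- Filter(function(b) b$nontrivial, bl)
  quasi_binary <- (length(hyb) == 0L || all(ind[hyb] == 2L & outd[hyb] == 1L)) &&
    all(vapply(nontriv, function(b) outd[[b$max_vertex]] == 2L, logical(1)))
  conv_leaf <- all(ind[N$leaves] <= 1L)
  conv_hyb <- all(vapply(hyb, function(h)
    sum(vapply(nontriv, function(b) h %in% b$vertices, logical(1))) == 1L,
    logical(1)))
  conventional <- conv_leaf && (length(hyb) == 0L || conv_hyb)
  shortcut_free <- nrow(shortcuts(N)) == 0L
  list(phylogenetic = phylogenetic, separated = separated, binary = binary,
       quasi_binary = quasi_binary, conventional = conventional,
       shortcut_free = shortcut_free)
}

#' Tree-child and normal networks
#'
#' A network is tree-child if every inner vertex has at least one child of
#' indegree 1; it is normal if it is tree-child and shortcut-free.
#'
#' @param N a `phynet`
#' @return logical scalar
#' @export
is_tree_child <- function(N) {
  ind <- nw_indeg(N); outd <- nw_outdeg(N)
  inner <- names(which(outd > 0L))
  all(vapply(inner, function(v) any(ind[nw_children(N, v)] == 1L), logical(1)))
}

#' @rdname is_tree_child
#' @export
is_normal <- function(N) is_tree_child(N) && nrow(shortcuts(N)) == 0L

#' Tree-based networks
#'
#' A network is tree-based if it admits a rooted spanning tree whose leaves
#' are exactly the leaves of the network, i.e. a choice of exactly one
#' incoming arc per non-root vertex under which every inner vertex keeps at
#' least one outgoing arc.  A tree vertex always retains the arc to any
#' child of indegree 1, so only the omnians -- inner vertices all of whose
#' children are hybrid -- are at risk of becoming dummy leaves.  The decision
#' therefore reduces to a bipartite matching between the omnians and their
#' children that saturates the omnians.
#'
#' @param N a `phynet`
#' @return list with `tree_based` (logical) and, when `TRUE`, `base_tree`:
#'   a two-column arc matrix of a witness spanning tree.  Matching ties are
#'   broken towards lexicographically smaller vertex ids so the witness is
#'   deterministic.
#' @export
is_tree_based <- function(N) {
  ind <- nw_indeg(N)
  omn <- omnians(N)
  if (length(omn) == 0L) {
    return(list(tree_based = TRUE, base_tree = default_spanning_tree(N, character(0))))
  }
  kids <- sort(unique(unlist(lapply(omn, function(v) nw_children(N, v)))))
  el <- do.call(rbind, lapply(sort(omn), function(v)
    cbind(paste0("O\r", v), paste0("C\r", nw_children(N, v)))))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  types <- startsWith(igraph::V(g)$name, "C\r")
  m <- igraph::max_bipartite_match(g, types = types)
  if (m$matching_size < length(omn))
    return(list(tree_based = FALSE, base_tree = NULL))
  match_named <- m$matching
  assigned <- stats::setNames(
    sub("^O\r", "", match_named[paste0("C\r", kids)]),
    kids)
  assigned <- assigned[!is.na(assigned)]
  list(tree_based = TRUE, base_tree = default_spanning_tree(N, assigned))
}

# inner vertices all of whose children are hybrid
omnians <- function(N) {
  ind <- nw_indeg(N); outd <- nw_outdeg(N)
  inner <- names(which(outd > 0L))
  inner[vapply(inner, function(v) all(ind[nw_children(N, v)] > 1L), logical(1))]
}

# one in-arc per non-root vertex; `assigned` maps some hybrid children to the
# parent they must keep, everything else takes the smallest parent id
default_spanning_tree <- function(N, assigned) {
  picks <- lapply(setdiff(N$vertices, N$root), function(v) {
    p <- if (v %in% names(assigned)) assigned[[v]] else min(nw_parents(N, v))
    c(p, v)
  })
  if (length(picks) == 0L) return(matrix(character(0), 0, 2))
  do.call(rbind, picks)
}

#' Galled trees
#'
#' A galled tree is a network in which every non-trivial block is an
#' undirected cycle; equivalently a level-1 network all of whose hybrid
#' vertices have indegree 2.
#'
#' @param N a `phynet`
#' @return logical scalar
#' @export
is_galled_tree <- function(N) {
  bl <- Filter(function(b) b$nontrivial, blocks(N))
  all(vapply(bl, function(b) {
    if (nrow(b$arcs) != length(b$vertices)) return(FALSE)
    deg <- table(factor(c(b$arcs[, 1L], b$arcs[, 2L]), levels = b$vertices))
    all(deg == 2L)
  }, logical(1)))
}
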