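# Graph rewrites and canonical constructions.  All operations preserve the
# ids of surviving vertices: arc expansion adds a fresh id derived from the
# expanded vertex, contraction deletes the upper vertex of the arc and keeps
# the lower one.

rebuild <- function(edges, labels = NULL, isolated_root = NULL) {
  build_network(edges, leaf_labels = labels, isolated_root = isolated_root)
}

fresh_id <- function(N, base, tag) {
  k <- 1L
  repeat {
    cand <- sprintf("%s__%s%d", base, tag, k)
    if (!(cand %in% N$vertices)) return(cand)
    k <- k + 1L
  }
}

#' Arc expansion
#'
#' `expd(N, w)` creates a fresh vertex `w'` that inherits all in-arcs of `w`
#' and becomes its single parent.  The clustering system, the ancestor order
#' on the old vertices, shortcut-freeness and the level are all preserved.
#' Applied to the root it creates a new root above the old one.
#'
#' @param N a `phynet`
#' @param w vertex id to expand
#' @return a new `phynet`; the fresh vertex is named `<w>__exp<k>`
#' @export
expd <- function(N, w) {
  if (!(w %in% N$vertices)) phyclus_stop("UnknownVertex", paste("unknown vertex", w))
  wp <- fresh_id(N, w, "exp")
  e <- N$edges
  into_w <- e[, 2L] == w
  e[into_w, 2L] <- wp
  e <- rbind(e, c(wp, w))
  rebuild(e, labels = N$labels)
}

#' Arc contraction
#'
#' `cntr(N, arc)` contracts the arc `(v', v)`: the upper vertex `v'` is
#' deleted and its remaining in- and out-arcs are re-attached to `v`,
#' silently dropping would-be parallel arcs.  Contracting a shortcut would
#' create a directed cycle and is rejected.
#'
#' @param N a `phynet`
#' @param arc length-2 character vector `c(v_prime, v)`
#' @return a new `phynet` without `v'`
#' @export
cntr <- function(N, arc) {
  vp <- arc[[1L]]; v <- arc[[2L]]
  if (!nw_has_arc(N, vp, v))
    phyclus_stop("UnknownArc", sprintf("(%s, %s) is not an arc of N", vp, v))
  if (is_shortcut(N, c(vp, v)))
    phyclus_stop("ShortcutContraction", "cannot contract a shortcut arc")
  e <- N$edges
  e <- e[!(e[, 1L] == vp & e[, 2L] == v), , drop = FALSE]
  e[e[, 1L] == vp, 1L] <- v
  e[e[, 2L] == vp, 2L] <- v
  e <- e[e[, 1L] != e[, 2L], , drop = FALSE]
  e <- e[!duplicated(paste(e[, 1L], e[, 2L], sep = "\r")), , drop = FALSE]
  if (nrow(e) == 0L) {
    lab <- if (v %in% names(N$labels)) N$labels[v] else stats::setNames(v, v)
    return(rebuild(NULL, labels = lab, isolated_root = v))
  }
  # v may have become a leaf or stopped being one; refresh the label map
  verts <- unique(c(e[, 1L], e[, 2L]))
  leaves <- setdiff(verts, e[, 1L])
  labs <- N$labels[intersect(names(N$labels), leaves)]
  newleaves <- setdiff(leaves, names(labs))
  labs <- c(labs, stats::setNames(newleaves, newleaves))
  rebuild(e, labels = labs)
}

#' Suppression of superfluous vertices
#'
#' `phylo_reduce` repeatedly contracts arcs `(u, w)` where `u` has outdegree
#' 1 and indegree at most 1 until the network is phylogenetic; clusters are
#' preserved and the level never increases.  `cntr_star` contracts a given
#' non-shortcut arc and then applies `phylo_reduce`.
#'
#' @param N a `phynet`
#' @param arc for `cntr_star`, the arc to contract first
#' @return a phylogenetic `phynet`
#' @export
phylo_reduce <- function(N) {
  repeat {
    ind <- nw_indeg(N); outd <- nw_outdeg(N)
    off <- names(which(outd == 1L & ind <= 1L))
    if (length(off) == 0L) return(N)
    u <- off[[1L]]
    N <- cntr(N, c(u, nw_children(N, u)[[1L]]))
  }
}

#' @rdname phylo_reduce
#' @export
cntr_star <- function(N, arc) phylo_reduce(cntr(N, arc))

#' Shortcut removal
#'
#' Deletes a shortcut arc.  The vertex set, all per-vertex clusters and the
#' ancestor relation are unchanged.
#'
#' @param N a `phynet`
#' @param arc length-2 character vector; must be a shortcut
#' @return a new `phynet`
#' @export
remove_shortcut <- function(N, arc) {
  u <- arc[[1L]]; w <- arc[[2L]]
  if (!nw_has_arc(N, u, w))
    phyclus_stop("UnknownArc", sprintf("(%s, %s) is not an arc of N", u, w))
  if (!is_shortcut(N, c(u, w)))
    phyclus_stop("NotAShortcut", sprintf("(%s, %s) is not a shortcut", u, w))
  e <- N$edges[!(N$edges[, 1L] == u & N$edges[, 2L] == w), , drop = FALSE]
  rebuild(e, labels = N$labels)
}

# ---- Hasse diagram / regular network ---------------------------------------

hasse_vertex_id <- function(members) {
  if (length(members) == 1L) members else
    paste0("{", paste(sort(members), collapse = ","), "}")
}

#' Regular network of a clustering system
#'
#' The Hasse diagram of the inclusion order of the clusters, with singleton
#' clusters relabelled by their taxon, is the unique regular network whose
#' clustering system equals `CS`.  It is shortcut-free, satisfies (PCC) and
#' has no outdegree-1 vertex.
#'
#' @param CS a `clustsys`
#' @return a `phynet`; non-singleton clusters become vertices named
#'   `"{a,b,...}"`, singletons keep their taxon label as id
#' @export
hasse <- function(CS) {
  if (length(CS$clusters) == 1L) {
    # single taxon: the one-vertex network
    return(rebuild(NULL, isolated_root = CS$X))
  }
  cov <- cs_covers(CS)
  ids <- vapply(CS$clusters, hasse_vertex_id, character(1))
  names(ids) <- cov$keys
  arcs <- list()
  for (i in seq_along(CS$clusters)) {
    for (pk in cov$parents[[i]]) {
      arcs[[length(arcs) + 1L]] <- c(ids[[pk]], ids[[cov$keys[i]]])
    }
  }
  rebuild(do.call(rbind, arcs))
}

#' Regularization of a (PCC) network
#'
#' Repeatedly removes shortcuts and contracts arcs out of outdegree-1
#' vertices until neither operation applies.  For networks satisfying
#' path-cluster comparability the result is the unique regular network of
#' the clustering system, independent of the order of operations.
#'
#' @param N a `phynet` satisfying (PCC)
#' @param check if `TRUE` (default) a violation of (PCC) is an error; the
#'   raw rewrite loop can be run on any network with `check = FALSE`
#' @return a regular `phynet`
#' @export
regularize <- function(N, check = TRUE) {
  if (check && !is_pcc(N))
    phyclus_stop("PccViolation", "regularize requires the (PCC) property")
  repeat {
    sc <- shortcuts(N)
    if (nrow(sc) > 0L) { N <- remove_shortcut(N, sc[1L, ]); next }
    outd <- nw_outdeg(N)
    o1 <- names(which(outd == 1L))
    if (length(o1) == 0L) return(N)
    u <- o1[[1L]]
    N <- cntr(N, c(u, nw_children(N, u)[[1L]]))
  }
}

#' Cluster network of a clustering system
#'
#' The unique semi-regular, separated, phylogenetic network displaying
#' exactly the clusters of `CS`: the regular network with every hybrid
#' vertex expanded.
#'
#' @param CS a `clustsys`
#' @return a `phynet`
#' @export
cluster_network_of <- function(CS) {
  N <- hasse(CS)
  for (h in nw_hybrids(N)) N <- expd(N, h)
  N
}

# ---- isomorphism -----------------------------------------------------------

# Joint colour refinement of two networks; returns integer colour vectors.
refine_colors <- function(N1, N2, fix_leaves) {
  init <- function(N) {
    ind <- nw_indeg(N); outd <- nw_outdeg(N)
    vapply(N$vertices, function(v) {
      if (outd[[v]] == 0L && fix_leaves)
        paste0("L:", N$labels[[v]])
      else paste0("d:", ind[[v]], ":", outd[[v]])
    }, character(1))
  }
  sig <- function(N, col) {
    vapply(N$vertices, function(v) {
      paste(col[[v]],
            paste(sort(col[nw_children(N, v)]), collapse = ","),
            paste(sort(col[nw_parents(N, v)]), collapse = ","),
            sep = "|")
    }, character(1))
  }
  c1 <- init(N1); c2 <- init(N2)
  names(c1) <- N1$vertices; names(c2) <- N2$vertices
  repeat {
    s1 <- sig(N1, c1); s2 <- sig(N2, c2)
    lev <- sort(unique(c(s1, s2)))
    n1 <- stats::setNames(as.character(match(s1, lev)), N1$vertices)
    n2 <- stats::setNames(as.character(match(s2, lev)), N2$vertices)
    # refinement never merges classes: a constant class count means stability
    if (length(unique(c(n1, n2))) == length(unique(c(c1, c2))))
      return(list(c1 = n1, c2 = n2))
    c1 <- n1; c2 <- n2
  }
}

#' Network isomorphism
#'
#' Decides whether two networks are isomorphic as leaf-labelled DAGs
#' (`fix_leaves = TRUE`: the bijection must map every leaf to the leaf with
#' the same label) or as plain directed graphs (`fix_leaves = FALSE`).
#' Colour refinement seeded with leaf labels and degrees narrows the search;
#' a backtracking step completes it.  Returns a witness bijection or `NULL`.
#'
#' @param N1,N2 `phynet` objects
#' @param fix_leaves logical
#' @return named character vector mapping `V(N1)` to `V(N2)`, or `NULL`
#' @export
isomorphic <- function(N1, N2, fix_leaves = TRUE) {
  if (length(N1$vertices) != length(N2$vertices) ||
      nrow(N1$edges) != nrow(N2$edges)) return(NULL)
  if (fix_leaves && !identical(leaf_set(N1), leaf_set(N2))) return(NULL)
  cols <- refine_colors(N1, N2, fix_leaves)
  t1 <- sort(table(cols$c1)); t2 <- sort(table(cols$c2))
  if (!identical(names(t1), names(t2)) || !identical(as.integer(t1), as.integer(t2)))
    return(NULL)
  has1 <- function(u, w) nw_has_arc(N1, u, w)
  adj2 <- new.env(parent = emptyenv())
  apply(N2$edges, 1L, function(r) assign(paste(r[1L], r[2L], sep = "\r"), TRUE, adj2))
  has2 <- function(u, w) !is.null(get0(paste(u, w, sep = "\r"), adj2))
  ord <- N1$vertices[order(as.integer(table(cols$c1)[cols$c1[N1$vertices]]),
                           N1$vertices)]
  mapping <- character(0)
  used <- character(0)
  bt <- function(i) {
    if (i > length(ord)) return(TRUE)
    v <- ord[[i]]
    cands <- setdiff(N2$vertices[cols$c2 == cols$c1[[v]]], used)
    if (fix_leaves && v %in% N1$leaves)
      cands <- intersect(cands, N2$leaves[unname(N2$labels[N2$leaves]) == N1$labels[[v]]])
    for (w in cands) {
      ok <- TRUE
      for (u in names(mapping)) {
        if (has1(u, v) != has2(mapping[[u]], w) ||
            has1(v, u) != has2(w, mapping[[u]])) { ok <- FALSE; break }
      }
      if (ok) {
        mapping[[v]] <<- w
        used <<- c(used, w)
        if (bt(i + 1L)) return(TRUE)
        mapping <<- mapping[names(mapping) != v]
        used <<- setdiff(used, w)
      }
    }
    FALSE
  }
  if (bt(1L)) mapping[N1$vertices] else NULL
}

# ---- phi_PCC ---------------------------------------------------------------

#' Positional vertex map between networks with equal cluster multisets
#'
#' For two networks satisfying (PCC) with identical cluster multisets, the
#' vertices displaying any fixed cluster form a chain in each network;
#' `phi_pcc` sorts both chains by the ancestor order and maps positionally.
#' The resulting bijection preserves clusters, fixes the leaves and preserves
#' the strict ancestor order; for semi-regular networks it is a graph
#' isomorphism.
#'
#' @param N1,N2 `phynet` objects satisfying (PCC) with equal multisets
#' @return named character vector mapping `V(N1)` to `V(N2)`
#' @export
phi_pcc <- function(N1, N2) {
  if (!is_pcc(N1) || !is_pcc(N2))
    phyclus_stop("PccViolation", "phi_pcc requires both networks to satisfy (PCC)")
  M1 <- cluster_multiset(N1); M2 <- cluster_multiset(N2)
  if (!multiset_equal(M1, M2))
    phyclus_stop("MultisetMismatch", "cluster multisets differ")
  r1 <- nw_reach(N1); r2 <- nw_reach(N2)
  cl1 <- nw_clusters(N1, r1); cl2 <- nw_clusters(N2, r2)
  k1 <- vapply(cl1, cl_key, character(1))
  k2 <- vapply(cl2, cl_key, character(1))
  out <- character(0)
  for (k in unique(k1)) {
    v1 <- names(k1)[k1 == k]
    v2 <- names(k2)[k2 == k]
    # ascending: minimal element first in both chains
    o1 <- v1[order(vapply(v1, function(v) sum(r1[v, v1]), integer(1)))]
    o2 <- v2[order(vapply(v2, function(v) sum(r2[v, v2]), integer(1)))]
    out[o1] <- o2
  }
  out[N1$vertices]
}
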