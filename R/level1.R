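# Level-1 theory: identification of the blocks of the Hasse diagram directly
# from the clusters, the closed + (L) characterisation, the compatibility
# test with network construction, and the galled / binary subclasses.

#' Overlap-block sets of a cluster
#'
#' For a cluster `C` of a clustering system, the set `b0` collects the
#' clusters whose pairwise overlap-intersection equals `C`; `u_set` is their
#' union, `top` its closure (or, when `b0` is empty, the unique inclusion-
#' minimal strict superset of `C`, which exists and is unique in a closed
#' system), and `bcal = b0 + {C, top}` is the vertex set of the block of the
#' Hasse diagram at `C`.  `d` and `dbar` split the remaining clusters into
#' strict subsets of `C` and clusters not contained in `C`; together with
#' `C` itself they partition the system.
#'
#' @param CS a `clustsys`
#' @param C character vector, a cluster of `CS`
#' @return list with components `b0`, `u_set`, `top`, `bcal`, `d`, `dbar`
#' @export
overlap_block_sets <- function(CS, C) {
  C <- sort(unique(as.character(C)))
  if (!cs_has(CS, C)) phyclus_stop("NotACluster", "C is not a cluster of CS")
  cls <- CS$clusters
  kC <- cl_key(C)
  others <- Filter(function(D) cl_key(D) != kC, cls)
  b0 <- Filter(function(Cp) {
    any(vapply(others, function(Cpp) {
      cl_key(Cpp) != cl_key(Cp) &&
        identical(cl_key(intersect(Cp, Cpp)), kC) &&
        overlaps(Cp, Cpp)
    }, logical(1)))
  }, others)
  if (length(b0) > 0L) {
    u_set <- sort(unique(unlist(b0)))
    top <- closure_of(CS, u_set)
  } else if (identical(C, CS$X)) {
    u_set <- character(0)
    top <- CS$X
  } else {
    u_set <- character(0)
    sup <- Filter(function(D) length(D) > length(C) && all(C %in% D), cls)
    mins <- Filter(function(D) !any(vapply(sup, function(E)
      length(E) < length(D) && all(E %in% D), logical(1))), sup)
    if (length(mins) != 1L)
      phyclus_stop("NotClosedForTop",
                   "no unique minimal strict superset; CS is not closed at C")
    top <- mins[[1L]]
  }
  d <- Filter(function(D) cl_key(D) != kC && all(D %in% C), cls)
  dbar <- Filter(function(D) !all(D %in% C), cls)
  bcal_keys <- unique(c(vapply(b0, cl_key, character(1)), kC, cl_key(top)))
  bcal <- cl_sort(lapply(bcal_keys, function(k) strsplit(k, "\r", fixed = TRUE)[[1L]]))
  list(b0 = cl_sort(b0), u_set = u_set, top = top, bcal = bcal,
       d = cl_sort(d), dbar = cl_sort(dbar))
}

#' Blocks of the Hasse diagram computed from the clusters alone
#'
#' For a closed clustering system satisfying property (L), the non-trivial
#' blocks of the Hasse diagram are exactly the sets `bcal(C)` of clusters
#' `C` with non-empty `b0(C)`, and the trivial blocks are the cover arcs
#' `(Top(C), C)` of the clusters that overlap nothing and have empty
#' `b0(C)`.  The result agrees vertex-set-wise with `blocks(hasse(CS))`.
#'
#' @param CS a closed `clustsys` satisfying (L)
#' @return list of blocks, each a list of clusters (for a one-taxon system,
#'   the single singleton)
#' @export
level1_blocks_from_clusters <- function(CS) {
  fl <- cs_flags(CS)
  if (!is_closed(CS) || !fl$property_L)
    phyclus_stop("PreconditionViolated",
                 "requires a closed clustering system satisfying (L)")
  if (length(CS$X) == 1L) return(list(CS$clusters))
  out <- list()
  for (C in CS$clusters) {
    obs <- overlap_block_sets(CS, C)
    if (length(obs$b0) > 0L) {
      out[[length(out) + 1L]] <- obs$bcal
    } else if (!identical(C, CS$X) &&
               !any(vapply(CS$clusters, function(D) overlaps(C, D), logical(1)))) {
      out[[length(out) + 1L]] <- cl_sort(list(C, obs$top))
    }
  }
  out
}

#' Characterisations of level-1 clustering systems
#'
#' A clustering system is displayed by a level-1 network iff it is closed
#' and satisfies (L); by a galled tree iff additionally (N3O) holds; and by
#' a binary level-1 network iff it is closed and satisfies (L) and (2-Inc).
#'
#' @param CS a `clustsys`
#' @return logical scalar
#' @export
is_level1_system <- function(CS) {
  is_closed(CS) && cs_flags(CS)$property_L
}

#' @rdname is_level1_system
#' @export
is_galled_system <- function(CS) {
  fl <- cs_flags(CS)
  is_closed(CS) && fl$property_L && fl$n3o
}

#' @rdname is_level1_system
#' @export
is_binary_l1_system <- function(CS) {
  fl <- cs_flags(CS)
  is_closed(CS) && fl$property_L && fl$two_inc
}

#' Level-1 compatibility of a clustering system
#'
#' A clustering system is compatible with a (separated, phylogenetic)
#' level-1 network -- i.e. some such network displays all of its clusters --
#' exactly when it satisfies property (L).  In the affirmative case a
#' witness network is built as the cluster network of the intersection
#' closure, whose clustering system is exactly that closure.
#'
#' @param CS a `clustsys`
#' @return list with `compatible` (logical), `network` (a `phynet` or
#'   `NULL`), `closure` (the intersection closure when compatible) and
#'   `n_clusters_added` (clusters added by the closure)
#' @export
check_l1_compatibility <- function(CS) {
  if (!cs_flags(CS)$property_L)
    return(list(compatible = FALSE, network = NULL, closure = NULL,
                n_clusters_added = NA_integer_))
  I <- intersection_closure(CS)
  N <- cluster_network_of(I)
  stopifnot(network_level(N) <= 1L, cs_equal(clustering_system(N), I))
  list(compatible = TRUE, network = N, closure = I,
       n_clusters_added = length(I$clusters) - length(CS$clusters))
}

#' Binary level-1 compatibility
#'
#' A clustering system is compatible with a binary level-1 network iff it
#' satisfies (L) and every hybrid vertex of the Hasse diagram of its
#' intersection closure has indegree exactly 2.  The witness network is the
#' binary resolution of the cluster network of the closure.
#'
#' @param CS a `clustsys`
#' @return list with `compatible` and `network`
#' @export
binary_l1_compatible <- function(CS) {
  if (!cs_flags(CS)$property_L)
    return(list(compatible = FALSE, network = NULL))
  I <- intersection_closure(CS)
  H <- hasse(I)
  ind <- nw_indeg(H)
  hyb <- names(which(ind > 1L))
  if (length(hyb) > 0L && any(ind[hyb] != 2L))
    return(list(compatible = FALSE, network = NULL))
  N <- resolve_to_binary(H)
  stopifnot(structural_flags(N)$binary, network_level(N) <= 1L)
  list(compatible = TRUE, network = N)
}

#' Binary resolution of a level-1 network
#'
#' Refines a level-1 network whose hybrid vertices all have indegree 2 into
#' a binary level-1 network whose clustering system contains the original
#' one.  Hybrid vertices of outdegree other than 1 are first expanded; every
#' remaining vertex of outdegree greater than 2 is then replaced by a
#' caterpillar over its non-block children plus one slot per cycle block
#' rooted at it, re-attaching each block's two cycle children beneath the
#' corresponding slot.  Caterpillar items are chained in order of the
#' smallest leaf label below them, so the output is deterministic.
#'
#' @param N a level-1 `phynet` with all hybrid indegrees equal to 2
#' @return a binary level-1 `phynet`
#' @export
resolve_to_binary <- function(N) {
  if (network_level(N) > 1L)
    phyclus_stop("NotLevel1", "resolve_to_binary requires a level-1 network")
  ind <- nw_indeg(N)
  hyb <- names(which(ind > 1L))
  if (any(ind[hyb] > 2L))
    phyclus_stop("HybridIndegreeTooHigh",
                 "all hybrid vertices must have indegree 2")
  for (h in hyb) {
    if (nw_outdeg(N)[[h]] != 1L) N <- expd(N, h)
  }
  repeat {
    outd <- nw_outdeg(N)
    big <- names(which(outd > 2L))
    if (length(big) == 0L) break
    N <- resolve_vertex(N, big[[1L]])
  }
  N
}

# caterpillar replacement of one vertex with outdegree > 2
resolve_vertex <- function(N, v) {
  reach <- nw_reach(N)
  cls <- nw_clusters(N, reach)
  kids <- sort(nw_children(N, v))
  bl <- Filter(function(b) b$nontrivial && identical(b$max_vertex, v), blocks(N))
  items <- list()
  cycle_kids <- character(0)
  for (b in bl) {
    two <- intersect(kids, b$vertices)
    cycle_kids <- c(cycle_kids, two)
    items[[length(items) + 1L]] <- list(kind = "block", children = sort(two))
  }
  for (k in setdiff(kids, cycle_kids)) {
    items[[length(items) + 1L]] <- list(kind = "single", children = k)
  }
  minlab <- vapply(items, function(it)
    min(unlist(cls[it$children])), character(1))
  items <- items[order(minlab)]
  e <- N$edges
  e <- e[e[, 1L] != v, , drop = FALSE]
  used <- N$vertices
  next_id <- local({
    k <- 0L
    function(tag) {
      repeat {
        k <<- k + 1L
        cand <- sprintf("%s__%s%d", v, tag, k)
        if (!(cand %in% used)) { used <<- c(used, cand); return(cand) }
      }
    }
  })
  cur <- v
  attach_item <- function(e, parent, item) {
    if (item$kind == "single") {
      rbind(e, c(parent, item$children))
    } else {
      s <- next_id("slot")
      rbind(e, c(parent, s), cbind(s, item$children))
    }
  }
  for (i in seq_along(items)) {
    if (i < length(items) - 1L) {
      e <- attach_item(e, cur, items[[i]])
      nxt <- next_id("cat")
      e <- rbind(e, c(cur, nxt))
      cur <- nxt
    } else {
      e <- attach_item(e, cur, items[[i]])
    }
  }
  rebuild(e, labels = N$labels)
}

#' Least-resolved level-1 network
#'
#' The unique regular network with the same clustering system as a level-1
#' network `N`, obtained by repeatedly removing shortcuts and contracting
#' arcs out of outdegree-1 vertices.  For level-1 networks regular and
#' least-resolved coincide, and the result equals the Hasse diagram of the
#' clustering system.
#'
#' @param N a level-1 `phynet`
#' @return a regular level-1 `phynet`
#' @export
least_resolved_level1 <- function(N) {
  if (network_level(N) > 1L)
    phyclus_stop("NotLevel1", "requires a level-1 network")
  regularize(N, check = FALSE)
}
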