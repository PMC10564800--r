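# Clustering systems: sets of leaf-label subsets containing the ground set X
# and all singletons.  Clusters are stored canonically as sorted character
# vectors; the list of clusters is sorted by (size, lexicographic key) so that
# equality and multiset counting are deterministic.

cl_key <- function(members) paste(sort(members), collapse = "\r")

cl_sort <- function(clusters) {
  keys <- vapply(clusters, cl_key, character(1))
  ord <- order(lengths(clusters), keys)
  clusters[ord]
}

#' Construct a clustering system
#'
#' A clustering system on a ground set `X` is a set of non-empty subsets of
#' `X` ("clusters") that contains `X` itself and every singleton.  The empty
#' set is never a cluster.
#'
#' @param clusters list of character vectors (the clusters)
#' @param X optional ground set; defaults to the union of the clusters
#' @param auto_complete if `TRUE` (default) the ground set and all singletons
#'   are added when missing (the object records whether this happened in
#'   attribute `completed`); if `FALSE`, their absence is an error.
#' @return object of class `clustsys`: a list with components `X` (sorted
#'   character vector) and `clusters` (canonically sorted list of sorted
#'   character vectors)
#' @export
clustsys <- function(clusters, X = NULL, auto_complete = TRUE) {
  clusters <- lapply(clusters, function(m) sort(unique(as.character(m))))
  if (any(lengths(clusters) == 0L))
    phyclus_stop("InvalidClusteringSystem", "the empty set cannot be a cluster")
  if (is.null(X)) X <- sort(unique(unlist(clusters)))
  else X <- sort(unique(as.character(X)))
  if (length(X) == 0L)
    phyclus_stop("InvalidClusteringSystem", "ground set is empty")
  if (!all(unlist(clusters) %in% X))
    phyclus_stop("NotSubsetOfGroundSet", "cluster members outside the ground set")
  keys <- vapply(clusters, cl_key, character(1))
  clusters <- clusters[!duplicated(keys)]
  keys <- unique(keys)
  required <- c(list(X), lapply(X, identity))
  missing <- required[!vapply(required, cl_key, character(1)) %in% keys]
  if (length(missing) > 0L) {
    if (!auto_complete)
      phyclus_stop("InvalidClusteringSystem",
                   "ground set or singletons missing (strict mode)")
    clusters <- c(clusters, missing)
  }
  structure(list(X = X, clusters = cl_sort(clusters)),
            class = "clustsys",
            completed = length(missing) > 0L)
}

#' @export
print.clustsys <- function(x, ...) {
  cat(sprintf("<clustering system on %d taxa, %d clusters>\n",
              length(x$X), length(x$clusters)))
  invisible(x)
}

cs_keys <- function(CS) vapply(CS$clusters, cl_key, character(1))

cs_has <- function(CS, members) cl_key(members) %in% cs_keys(CS)

cs_equal <- function(A, B) {
  identical(A$X, B$X) && identical(cs_keys(A), cs_keys(B))
}

#' Cluster of a vertex
#'
#' The (hardwired) cluster of a vertex `v` is the set of leaf labels
#' reachable from `v`.
#'
#' @param N a `phynet`
#' @param v vertex id
#' @return sorted character vector of leaf labels
#' @export
cluster_of <- function(N, v) {
  if (!(v %in% N$vertices)) phyclus_stop("UnknownVertex", paste("unknown vertex", v))
  reach <- nw_reach(N)
  sort(unname(N$labels[N$leaves[reach[v, N$leaves]]]))
}

# all clusters at once: named list vertex -> sorted label vector
nw_clusters <- function(N, reach = nw_reach(N)) {
  labs <- N$labels
  lv <- N$leaves
  out <- lapply(N$vertices, function(v) sort(unname(labs[lv[reach[v, lv]]])))
  names(out) <- N$vertices
  out
}

#' Clustering system and cluster multiset of a network
#'
#' `clustering_system(N)` collects the distinct clusters of all vertices of
#' `N` into a clustering system; `cluster_multiset(N)` counts, for each
#' cluster, the number of vertices displaying it (so the counts sum to the
#' number of vertices).
#'
#' @param N a `phynet`
#' @return `clustering_system`: a `clustsys`; `cluster_multiset`: a list with
#'   `clusters` (list of clusters) and `count` (integer vector)
#' @export
clustering_system <- function(N) {
  cls <- nw_clusters(N)
  clustsys(unname(cls), X = leaf_set(N), auto_complete = FALSE)
}

#' @rdname clustering_system
#' @export
cluster_multiset <- function(N) {
  cls <- nw_clusters(N)
  keys <- vapply(cls, cl_key, character(1))
  tab <- table(keys)
  uk <- names(tab)
  clusters <- cl_sort(lapply(uk, function(k) strsplit(k, "\r", fixed = TRUE)[[1L]]))
  counts <- as.integer(tab[vapply(clusters, cl_key, character(1))])
  list(clusters = clusters, count = counts)
}

multiset_equal <- function(M1, M2) {
  k1 <- vapply(M1$clusters, cl_key, character(1))
  k2 <- vapply(M2$clusters, cl_key, character(1))
  identical(k1, k2) && identical(M1$count, M2$count)
}

#' Closure operator of a clustering system
#'
#' `closure_of(CS, A)` is the intersection of all clusters containing `A`
#' (the ground set always qualifies).  It is enlarging, isotone and
#' idempotent; the closure of the empty set is empty whenever `|X| > 1`.
#'
#' @param CS a `clustsys`
#' @param A character vector, a subset of the ground set
#' @return sorted character vector
#' @export
closure_of <- function(CS, A) {
  A <- sort(unique(as.character(A)))
  if (!all(A %in% CS$X))
    phyclus_stop("NotSubsetOfGroundSet", "A is not a subset of the ground set")
  if (length(A) == 0L) {
    return(if (length(CS$X) > 1L) character(0) else CS$X)
  }
  res <- CS$X
  for (C in CS$clusters) {
    if (all(A %in% C)) res <- intersect(res, C)
  }
  sort(res)
}

#' Is a clustering system closed under intersection?
#'
#' A clustering system is closed iff every non-empty pairwise intersection of
#' clusters is itself a cluster (pairwise intersections suffice).
#'
#' @param CS a `clustsys`
#' @return logical scalar
#' @export
is_closed <- function(CS) {
  keys <- cs_keys(CS)
  n <- length(CS$clusters)
  if (n < 2L) return(TRUE)
  for (i in seq_len(n - 1L)) {
    Ci <- CS$clusters[[i]]
    for (j in (i + 1L):n) {
      I <- intersect(Ci, CS$clusters[[j]])
      if (length(I) > 0L && !(cl_key(I) %in% keys)) return(FALSE)
    }
  }
  TRUE
}

#' Intersection closure
#'
#' The least closed clustering system containing `CS`: all non-empty
#' intersections of clusters are added, iterating pairwise intersections to
#' a fixpoint (which is equivalent to closing under arbitrary intersections).
#' The empty set is never added.
#'
#' @param CS a `clustsys`
#' @return a closed `clustsys`
#' @export
intersection_closure <- function(CS) {
  clusters <- CS$clusters
  keys <- vapply(clusters, cl_key, character(1))
  repeat {
    added <- FALSE
    n <- length(clusters)
    for (i in seq_len(max(0L, n - 1L))) {
      for (j in (i + 1L):n) {
        I <- intersect(clusters[[i]], clusters[[j]])
        if (length(I) > 0L) {
          k <- cl_key(I)
          if (!(k %in% keys)) {
            clusters <- c(clusters, list(sort(I)))
            keys <- c(keys, k)
            added <- TRUE
          }
        }
      }
    }
    if (!added) break
  }
  clustsys(clusters, X = CS$X, auto_complete = FALSE)
}

overlaps <- function(A, B) {
  I <- intersect(A, B)
  length(I) > 0L && length(I) < length(A) && length(I) < length(B)
}

# Hasse cover relation: cover_parents[[k]] = keys of inclusion-minimal strict
# supersets of cluster k; cover_children analogous.
cs_covers <- function(CS) {
  n <- length(CS$clusters)
  keys <- cs_keys(CS)
  subset_of <- matrix(FALSE, n, n, dimnames = list(keys, keys))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) subset_of[i, j] <- all(CS$clusters[[i]] %in% CS$clusters[[j]]) &&
        length(CS$clusters[[i]]) < length(CS$clusters[[j]])
  }
  parents <- vector("list", n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    ups <- which(subset_of[i, ])
    # minimal elements among strict supersets
    cov <- ups[vapply(ups, function(j) !any(subset_of[ups, j]), logical(1))]
    parents[[i]] <- keys[cov]
    for (j in cov) children[[j]] <- c(children[[j]], keys[i])
  }
  list(keys = keys, parents = parents, children = children)
}

#' Predicates on clustering systems
#'
#' Evaluates the standard structural predicates of a clustering system:
#' \describe{
#'   \item{hierarchy}{no two clusters overlap}
#'   \item{pre_binary}{every leaf pair has a unique inclusion-minimal cluster
#'     containing it}
#'   \item{binary}{pre-binary, and every cluster is the minimal cluster of
#'     some leaf pair}
#'   \item{weak_hierarchy}{for every triple, the triple intersection equals
#'     one of the pairwise intersections}
#'   \item{property_L}{for every cluster, its intersections with all clusters
#'     it overlaps coincide}
#'   \item{n3o}{no three pairwise overlapping clusters}
#'   \item{paired_hierarchy}{every cluster overlaps at most one other}
#'   \item{two_inc}{every cluster has at most two cover-children and at most
#'     two cover-parents in the inclusion order}
#' }
#'
#' @param CS a `clustsys`
#' @return named list of logicals
#' @export
cs_flags <- function(CS) {
  cls <- CS$clusters
  n <- length(cls)
  ov <- matrix(FALSE, n, n)
  for (i in seq_len(max(0L, n - 1L))) for (j in (i + 1L):n) {
    o <- overlaps(cls[[i]], cls[[j]])
    ov[i, j] <- o; ov[j, i] <- o
  }
  hierarchy <- !any(ov)
  # property (L): all overlap-partner intersections of a cluster agree
  property_L <- TRUE
  for (i in seq_len(n)) {
    part <- which(ov[i, ])
    if (length(part) >= 2L) {
      ints <- unique(vapply(part, function(j)
        cl_key(intersect(cls[[i]], cls[[j]])), character(1)))
      if (length(ints) > 1L) { property_L <- FALSE; break }
    }
  }
  # (N3O): no triangle in the overlap graph
  n3o <- TRUE
  if (any(ov)) {
    for (i in seq_len(n)) {
      part <- which(ov[i, ])
      if (length(part) >= 2L) {
        pp <- ov[part, part, drop = FALSE]
        if (any(pp)) { n3o <- FALSE; break }
      }
    }
  }
  paired_hierarchy <- all(rowSums(ov) <= 1L)
  weak_hierarchy <- is_weak_hierarchy(CS)
  pb <- pre_binary_info(CS)
  covers <- cs_covers(CS)
  two_inc <- all(lengths(covers$parents) <= 2L) &&
    all(lengths(covers$children) <= 2L)
  list(hierarchy = hierarchy, pre_binary = pb$pre_binary, binary = pb$binary,
       weak_hierarchy = weak_hierarchy, property_L = property_L, n3o = n3o,
       paired_hierarchy = paired_hierarchy, two_inc = two_inc)
}

is_weak_hierarchy <- function(CS) {
  cls <- CS$clusters
  n <- length(cls)
  if (n < 3L) return(TRUE)
  for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) {
    Iij <- intersect(cls[[i]], cls[[j]])
    for (k in (j + 1L):n) {
      Iik <- intersect(cls[[i]], cls[[k]])
      Ijk <- intersect(cls[[j]], cls[[k]])
      T3 <- intersect(Iij, cls[[k]])
      kT <- cl_key(T3)
      if (kT != cl_key(Iij) && kT != cl_key(Iik) && kT != cl_key(Ijk))
        return(FALSE)
    }
  }
  TRUE
}

# minimal containing clusters per leaf pair; cost O(|X|^2 |C|), fine at desk
# scale
pre_binary_info <- function(CS) {
  X <- CS$X
  cls <- CS$clusters
  pre_binary <- TRUE
  witness <- character(0)
  for (i in seq_along(X)) for (j in i:length(X)) {
    pair <- unique(c(X[i], X[j]))
    cont <- Filter(function(C) all(pair %in% C), cls)
    mins <- Filter(function(C) !any(vapply(cont, function(D)
      length(D) < length(C) && all(D %in% C), logical(1))), cont)
    if (length(mins) != 1L) pre_binary <- FALSE
    else witness <- c(witness, cl_key(mins[[1L]]))
  }
  binary <- pre_binary && all(cs_keys(CS) %in% witness)
  list(pre_binary = pre_binary, binary = binary)
}

#' Pre-pyramidal clustering systems
#'
#' A clustering system is pre-pyramidal (an interval hypergraph) if there is
#' a total order of the ground set under which every cluster is an interval.
#' Under property (L) this is equivalent to the absence of three pairwise
#' overlapping clusters; without (L) the decision falls back to a
#' backtracking search over orders, permitted only for small ground sets.
#'
#' @param CS a `clustsys`
#' @param max_search largest ground set for which the exhaustive order search
#'   is attempted when (L) fails (default 10)
#' @return logical scalar
#' @export
is_pre_pyramidal <- function(CS, max_search = 10L) {
  fl <- cs_flags(CS)
  if (fl$property_L) return(fl$n3o)
  if (length(CS$X) > max_search)
    phyclus_stop("GroundSetTooLargeWithoutL",
                 "ground set too large for exhaustive order search without (L)")
  interval_order_exists(CS)
}

# backtracking placement: a partial prefix is feasible iff every cluster that
# meets the prefix but is not contained in it occupies a suffix of the prefix
interval_order_exists <- function(CS) {
  X <- CS$X
  cls <- Filter(function(C) length(C) > 1L && length(C) < length(X), CS$clusters)
  n <- length(X)
  ok_prefix <- function(prefix) {
    np <- length(prefix)
    for (C in cls) {
      inpos <- which(prefix %in% C)
      if (length(inpos) == 0L) next
      if (any(diff(inpos) != 1L)) return(FALSE)       # members not contiguous
      if (length(inpos) < length(C) && inpos[length(inpos)] != np)
        return(FALSE)                                  # open cluster not at end
    }
    TRUE
  }
  recurse <- function(prefix, rest) {
    if (length(rest) == 0L) return(TRUE)
    for (x in rest) {
      p2 <- c(prefix, x)
      if (ok_prefix(p2) && recurse(p2, setdiff(rest, x))) return(TRUE)
    }
    FALSE
  }
  recurse(character(0), X)
}
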