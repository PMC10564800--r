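# Brute-force oracles backing the property suites, and the exhaustive
# enumerator of small phylogenetic quasi-binary level-1 networks.  The
# oracles deliberately share no code with the algorithms they check.

#' Brute-force tree-based decision
#'
#' Enumerates every choice of one incoming arc per non-root vertex and
#' checks whether some choice leaves every inner vertex with at least one
#' outgoing arc.  Exponential in the number of hybrid vertices; restricted
#' to small instances.
#'
#' @param N a `phynet`
#' @param max_choices abort above this many parent-choice combinations
#' @return logical scalar
#' @export
oracle_tree_based <- function(N, max_choices = 2e5) {
  nonroot <- setdiff(N$vertices, N$root)
  if (length(nonroot) == 0L) return(TRUE)
  parents <- lapply(nonroot, function(v) sort(nw_parents(N, v)))
  n_comb <- prod(lengths(parents))
  if (n_comb > max_choices)
    phyclus_stop("InstanceTooLarge", "too many parent-choice functions")
  inner <- names(which(nw_outdeg(N) > 0L))
  idx <- rep(1L, length(parents))
  repeat {
    chosen <- vapply(seq_along(parents), function(i) parents[[i]][idx[i]],
                     character(1))
    if (all(inner %in% chosen)) return(TRUE)
    j <- 1L
    while (j <= length(idx)) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= length(parents[[j]])) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > length(idx)) return(FALSE)
  }
}

#' Brute-force LCA oracle
#'
#' Scans all vertices for common ancestors of a label set and strips the
#' non-minimal ones by pairwise comparison.
#'
#' @param N a `phynet`
#' @param A non-empty character vector of leaf labels
#' @return sorted character vector of vertex ids
#' @export
oracle_lca <- function(N, A) {
  A <- unique(as.character(A))
  if (length(A) == 0L) phyclus_stop("EmptyQuery", "query leaf set is empty")
  reach <- nw_reach(N)
  ca <- Filter(function(v) all(A %in% cluster_of(N, v)), N$vertices)
  keep <- Filter(function(v) {
    others <- setdiff(ca, v)
    !any(vapply(others, function(u) reach[v, u], logical(1)))
  }, ca)
  sort(unlist(keep))
}

# ---- exhaustive enumeration ------------------------------------------------

#' Enumerate small phylogenetic quasi-binary level-1 networks
#'
#' Recursively constructs, up to leaf-labelled isomorphism, every
#' phylogenetic quasi-binary level-1 network on a given leaf set.  The root
#' of every component is either a leaf, a tree vertex whose child components
#' carry a set partition of the taxa, or the maximum of an undirected cycle:
#' two chains meet in a terminal hybrid of indegree 2, every chain vertex
#' carries one or more child components, and the hybrid carries exactly one.
#' An empty second chain realises the shortcut chord from the cycle maximum
#' to its hybrid.  Duplicates (e.g. from reflecting a cycle) are removed by
#' invariant bucketing followed by pairwise isomorphism tests.
#'
#' @param leaves character vector of taxa (at most 5)
#' @param max_vertices discard networks with more vertices than this
#' @return list of pairwise non-isomorphic `phynet` objects
#' @export
enumerate_small_networks <- function(leaves, max_vertices = 12L) {
  leaves <- sort(unique(as.character(leaves)))
  if (length(leaves) > 5L)
    phyclus_stop("InstanceTooLarge", "enumeration limited to 5 leaves")
  if (length(leaves) == 1L)
    return(list(build_network(NULL, isolated_root = leaves)))
  comps <- enum_components(leaves, max_vertices, prefix = "t_")
  nets <- lapply(comps, function(cc) build_network(cc$edges))
  nets <- Filter(function(N) length(N$vertices) <= max_vertices, nets)
  dedup_networks(nets)
}

# A component is list(root = id, edges = matrix); for a single taxon the
# root is the taxon itself and the edge set is empty.
leaf_component <- function(x) list(root = x, edges = matrix(character(0), 0, 2))

enum_components <- function(S, max_v, prefix) {
  if (length(S) == 1L) return(list(leaf_component(S)))
  rid <- paste0(prefix, "r")
  out <- list()
  for (parts in set_partitions(S)) {
    if (length(parts) < 2L) next
    # (a) plain tree vertex at the root
    for (combo in cross_components(parts, max_v, prefix)) {
      e <- rid_edges(rid, combo)
      if (n_verts(e) <= max_v + 1L)
        out[[length(out) + 1L]] <- list(root = rid, edges = e)
    }
    # (b) cycle at the root: one part below the hybrid, the rest distributed
    # over the chain vertices
    for (hi in seq_along(parts)) {
      rest <- parts[-hi]
      for (asg in chain_assignments(length(rest))) {
        out <- c(out, cycle_components(rid, prefix, parts[[hi]], rest, asg, max_v))
      }
    }
  }
  out
}

rid_edges <- function(rid, combo) {
  do.call(rbind, c(list(matrix(character(0), 0, 2)),
                   lapply(combo, function(cc) rbind(c(rid, cc$root), cc$edges))))
}

# ordered assignments of parts 1..t to two chains of slots; each slot is a
# non-empty set of part indices; the left chain is non-empty, the right may
# be empty (shortcut chord)
chain_assignments <- function(t) {
  res <- list()
  for (osp in ordered_set_partitions(seq_len(t))) {
    j <- length(osp)
    for (cut in seq_len(j)) {
      res[[length(res) + 1L]] <- list(
        left = osp[seq_len(cut)],
        right = if (cut < j) osp[(cut + 1L):j] else list())
    }
  }
  res
}

cycle_components <- function(rid, prefix, h_part, rest, asg, max_v) {
  hid <- paste0(prefix, "h")
  nl <- length(asg$left); nr <- length(asg$right)
  left_ids <- if (nl > 0L) paste0(prefix, "p", seq_len(nl)) else character(0)
  right_ids <- if (nr > 0L) paste0(prefix, "q", seq_len(nr)) else character(0)
  chain <- function(ids) {
    nodes <- c(rid, ids, hid)
    cbind(nodes[-length(nodes)], nodes[-1L])
  }
  skeleton <- rbind(chain(left_ids), chain(right_ids))
  # flat list of (owner vertex, taxon part)
  owners <- c(hid,
              rep(left_ids, lengths(asg$left)),
              rep(right_ids, lengths(asg$right)))
  flat_parts <- c(list(h_part),
                  lapply(unlist(c(asg$left, asg$right)), function(i) rest[[i]]))
  out <- list()
  for (combo in cross_components(flat_parts, max_v, prefix)) {
    e <- skeleton
    for (i in seq_along(flat_parts)) {
      e <- rbind(e, c(owners[[i]], combo[[i]]$root), combo[[i]]$edges)
    }
    if (n_verts(e) <= max_v + 1L)
      out[[length(out) + 1L]] <- list(root = rid, edges = e)
  }
  out
}

# cartesian product of component choices per part; sub-component ids are
# prefixed "<prefix><i>_" so vertex ids never collide
cross_components <- function(parts, max_v, prefix) {
  per_part <- lapply(seq_along(parts), function(i) {
    enum_components(parts[[i]], max_v, paste0(prefix, i, "_"))
  })
  res <- list()
  idx <- rep(1L, length(parts))
  repeat {
    res[[length(res) + 1L]] <- lapply(seq_along(parts),
                                      function(i) per_part[[i]][[idx[i]]])
    j <- 1L
    while (j <= length(idx)) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= length(per_part[[j]])) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > length(idx)) break
  }
  res
}

n_verts <- function(e) length(unique(c(e)))

# all set partitions of a character vector (standard recursive scheme)
set_partitions <- function(S) {
  if (length(S) == 0L) return(list(list()))
  if (length(S) == 1L) return(list(list(S)))
  first <- S[[1L]]
  rest <- S[-1L]
  out <- list()
  for (p in set_partitions(rest)) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- sort(c(first, q[[i]]))
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(first), p)
  }
  out
}

# ordered sequences of the blocks of every set partition
ordered_set_partitions <- function(idx) {
  res <- list()
  for (p in set_partitions(idx)) {
    for (pr in permutations(length(p))) res[[length(res) + 1L]] <- p[pr]
  }
  res
}

permutations <- function(n) {
  if (n == 0L) return(list(integer(0)))
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# invariant bucketing + pairwise isomorphism
dedup_networks <- function(nets) {
  if (length(nets) <= 1L) return(nets)
  inv <- vapply(nets, function(N) {
    M <- cluster_multiset(N)
    paste(length(N$vertices), nrow(N$edges),
          paste(sort(paste(vapply(M$clusters, cl_key, character(1)),
                           M$count)), collapse = ";"),
          sep = "|")
  }, character(1))
  keep <- integer(0)
  for (b in split(seq_along(nets), inv)) {
    reps <- integer(0)
    for (i in b) {
      dup <- FALSE
      for (j in reps) {
        if (!is.null(isomorphic(nets[[i]], nets[[j]], fix_leaves = TRUE))) {
          dup <- TRUE; break
        }
      }
      if (!dup) reps <- c(reps, i)
    }
    keep <- c(keep, reps)
  }
  nets[sort(keep)]
}
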