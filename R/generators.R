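# Seeded random generators.  The level-1 generator grows a random
# phylogenetic tree and replaces chosen multi-child inner vertices by
# undirected cycles with a single terminal hybrid; by construction the
# output is phylogenetic, tree-child, shortcut-free (unless shortcuts are
# requested) and level-1, with quasi-binary blocks.

with_seed <- function(seed, code) {
  env <- globalenv()
  old <- get0(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = env)
    else assign(".Random.seed", old, envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Generator configuration
#'
#' @param n_leaves number of taxa (labels `l1 ... ln`)
#' @param n_blocks number of cycle blocks to insert
#' @param max_block_size largest cycle length (at least 4 when shortcuts are
#'   disallowed; 3-cycles necessarily contain a shortcut)
#' @param seed integer seed; identical configurations produce identical
#'   networks
#' @param force_binary refine the output into a binary level-1 network
#' @param force_separated expand hybrid vertices of outdegree other than 1
#'   (the raw construction is already separated, so this is a no-op safety)
#' @param allow_shortcuts additionally insert the chord from a cycle maximum
#'   to its hybrid in roughly half of the blocks
#' @return list of class `gencfg`
#' @export
generator_config <- function(n_leaves, n_blocks = 0L, max_block_size = 5L,
                             seed = 1L, force_binary = FALSE,
                             force_separated = FALSE, allow_shortcuts = FALSE) {
  if (n_leaves < 1L || n_blocks < 0L)
    phyclus_stop("InfeasibleConfig", "n_leaves >= 1 and n_blocks >= 0 required")
  if (n_blocks > 0L && max_block_size < 3L)
    phyclus_stop("InfeasibleConfig", "max_block_size >= 3 required with blocks")
  structure(list(n_leaves = as.integer(n_leaves), n_blocks = as.integer(n_blocks),
                 max_block_size = as.integer(max_block_size),
                 seed = as.integer(seed), force_binary = force_binary,
                 force_separated = force_separated,
                 allow_shortcuts = allow_shortcuts),
            class = "gencfg")
}

# random phylogenetic tree on labels l1..ln with a bias towards multi-child
# vertices (uniform attachment over a small pool of inner vertices)
random_fat_tree <- function(n) {
  if (n == 1L) return(build_network(NULL, isolated_root = "l1"))
  n_inner <- sample.int(max(1L, n %/% 3L), 1L)
  arcs <- list()
  inner <- paste0("i", seq_len(n_inner))
  if (n_inner > 1L) {
    for (k in 2:n_inner) {
      p <- inner[[sample.int(k - 1L, 1L)]]
      arcs[[length(arcs) + 1L]] <- c(p, inner[[k]])
    }
  }
  # every inner vertex gets at least one leaf, the rest land uniformly
  hosts <- c(inner, sample(inner, n - n_inner, replace = TRUE))
  leaves <- paste0("l", seq_len(n))
  for (i in seq_len(n)) arcs[[length(arcs) + 1L]] <- c(hosts[[i]], leaves[[i]])
  phylo_reduce(build_network(do.call(rbind, arcs)))
}

#' Random level-1 network
#'
#' Grows a seeded random phylogenetic tree on `n_leaves` taxa and converts
#' `n_blocks` inner vertices with enough children into undirected cycles:
#' the vertex becomes the cycle maximum, a fresh hybrid its terminal vertex,
#' and former subtrees hang off the cycle's interior vertices, so each
#' interior vertex keeps outdegree 2.  The result is a phylogenetic,
#' tree-child, separated level-1 network with quasi-binary blocks;
#' shortcut-free unless `allow_shortcuts` is set.
#'
#' @param cfg a `gencfg` from [generator_config()]
#' @return a `phynet`
#' @export
gen_random_level1 <- function(cfg) {
  stopifnot(inherits(cfg, "gencfg"))
  with_seed(cfg$seed, {
    N <- random_fat_tree(cfg$n_leaves)
    min_cycle <- if (cfg$allow_shortcuts) 3L else 4L
    if (cfg$n_blocks > 0L && cfg$max_block_size < min_cycle)
      phyclus_stop("InfeasibleConfig",
                   "max_block_size too small for shortcut-free cycles")
    blocks_left <- cfg$n_blocks
    bnum <- 0L
    while (blocks_left > 0L) {
      ind <- nw_indeg(N)
      # only children reached over cut arcs may be moved into a new cycle;
      # re-routing a cycle arc would merge two blocks and raise the level
      nt <- Filter(function(b) b$nontrivial, blocks(N))
      bound <- list()
      for (b in nt) {
        mx <- b$max_vertex
        bound[[mx]] <- c(bound[[mx]], intersect(nw_children(N, mx), b$vertices))
      }
      free_kids <- lapply(stats::setNames(N$vertices, N$vertices), function(v)
        setdiff(nw_children(N, v), bound[[v]]))
      # cycle of size m needs m - 2 interior vertices, each consuming one of
      # the free children as its subtree; one more child goes below the hybrid
      need_k <- min_cycle - 1L
      sites <- N$vertices[lengths(free_kids) >= need_k & ind <= 1L]
      sites <- setdiff(sites, N$leaves)
      if (length(sites) == 0L)
        phyclus_stop("InfeasibleConfig",
                     "not enough multi-child inner vertices for the requested blocks")
      v <- sample(sites, 1L)
      k <- length(free_kids[[v]])
      m_max <- min(cfg$max_block_size, k + 1L)
      m <- if (m_max > min_cycle) sample(min_cycle:m_max, 1L) else min_cycle
      N <- insert_cycle(N, v, m, bnum <- bnum + 1L, free_kids[[v]])
      blocks_left <- blocks_left - 1L
    }
    if (cfg$allow_shortcuts) {
      for (b in Filter(function(b) b$nontrivial, blocks(N))) {
        if (stats::runif(1) < 0.5 &&
            !nw_has_arc(N, b$max_vertex, b$terminal_vertices[[1L]])) {
          N <- rebuild(rbind(N$edges, c(b$max_vertex, b$terminal_vertices[[1L]])),
                       labels = N$labels)
        }
      }
    }
    if (cfg$force_separated) {
      for (h in nw_hybrids(N)) if (nw_outdeg(N)[[h]] != 1L) N <- expd(N, h)
    }
    if (cfg$force_binary) N <- resolve_to_binary(N)
    N
  })
}

# replace inner vertex v (>= m-1 free children) by a cycle of length m
# rooted at v
insert_cycle <- function(N, v, m, bnum, free_kids = nw_children(N, v)) {
  kids <- sort(free_kids)
  interior_n <- m - 2L
  chosen <- sample(kids, interior_n + 1L)
  hybrid_kid <- chosen[[1L]]
  interior_kids <- chosen[-1L]
  # both chains non-empty whenever possible; an empty right chain yields the
  # 3-cycle whose chord is a shortcut (only reachable with allow_shortcuts)
  left_n <- if (interior_n == 1L) 1L else sample.int(interior_n - 1L, 1L)
  right_n <- interior_n - left_n
  pre <- sprintf("%s__b%d", v, bnum)
  h <- paste0(pre, "_h")
  left <- if (left_n > 0L) paste0(pre, "_p", seq_len(left_n)) else character(0)
  right <- if (right_n > 0L) paste0(pre, "_q", seq_len(right_n)) else character(0)
  e <- N$edges
  drop <- e[, 1L] == v & e[, 2L] %in% chosen
  e <- e[!drop, , drop = FALSE]
  chain <- function(top, seq_ids, bottom) {
    nodes <- c(top, seq_ids, bottom)
    cbind(nodes[-length(nodes)], nodes[-1L])
  }
  e <- rbind(e, chain(v, left, h))
  if (right_n > 0L) e <- rbind(e, chain(v, right, h)) else e <- rbind(e, c(v, h))
  e <- rbind(e, c(h, hybrid_kid))
  carriers <- c(left, right)
  for (i in seq_along(interior_kids)) {
    e <- rbind(e, c(carriers[[i]], interior_kids[[i]]))
  }
  rebuild(e, labels = N$labels)
}

#' Star-with-bipartite-tail networks of prescribed level
#'
#' For `k = 0` a star tree on `n` leaves; for `k >= 2`, `k` of the star
#' leaves acquire arcs to `k` fresh leaves forming a complete bipartite
#' pattern.  The result is phylogenetic, shortcut-free, level-`k` but not
#' level-`(k-1)`, and its clustering system is a hierarchy -- showing that
#' hierarchies do not bound the level of the networks displaying them.
#'
#' @param n number of original star leaves (`n >= 1`)
#' @param k level; `k = 0` or `2 <= k <= n`
#' @return a `phynet`
#' @export
gen_star_bipartite <- function(n, k) {
  if (n < 1L || !(k == 0L || (k >= 2L && k <= n)))
    phyclus_stop("BadK", "k must be 0 or in 2..n")
  if (n == 1L) return(build_network(NULL, isolated_root = "l1"))
  leaves <- paste0("l", seq_len(n))
  arcs <- cbind("r", leaves)
  if (k >= 2L) {
    xs <- paste0("x", seq_len(k))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      arcs <- rbind(arcs, c(leaves[[i]], xs[[j]]))
    }
  }
  build_network(arcs)
}

#' Mutate a clustering system until property (L) fails
#'
#' Adds random non-trivial subsets of the ground set until the result
#' violates (L); used to produce negative instances for the compatibility
#' test.  Requires at least three taxa.
#'
#' @param CS a `clustsys` satisfying (L)
#' @param max_tries attempts before giving up
#' @return a `clustsys` violating (L)
#' @export
break_property_l <- function(CS, max_tries = 200L) {
  X <- CS$X
  if (length(X) < 3L)
    phyclus_stop("InfeasibleConfig", "need at least 3 taxa to break (L)")
  cur <- CS
  for (i in seq_len(max_tries)) {
    sz <- sample(2:(length(X) - 1L), 1L)
    A <- sort(sample(X, sz))
    if (cs_has(cur, A)) next
    cand <- clustsys(c(cur$clusters, list(A)), X = X, auto_complete = FALSE)
    if (!cs_flags(cand)$property_L) return(cand)
    cur <- cand
  }
  phyclus_stop("InfeasibleConfig", "could not break (L)")
}
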