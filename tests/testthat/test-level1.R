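test_that("overlap-block sets on the worked examples", {
  fx <- fixtures()
  CS <- clustering_system(fx$F_D1)
  obs <- overlap_block_sets(CS, "x")
  expect_setequal(vapply(obs$b0, paste, character(1), collapse = "|"),
                  c("x|y", "x|z"))
  expect_identical(obs$u_set, c("x", "y", "z"))
  expect_identical(obs$top, c("x", "y", "z"))
  expect_setequal(vapply(obs$bcal, paste, character(1), collapse = "|"),
                  c("x", "x|y", "x|z", "x|y|z"))

  CT <- clustering_system(fx$F_T3)
  o2 <- overlap_block_sets(CT, "1")
  expect_length(o2$b0, 0L)
  expect_identical(o2$top, c("1", "2"))

  oX <- overlap_block_sets(CS, CS$X)
  expect_identical(oX$top, CS$X)
  expect_length(oX$dbar, 0L)
  expect_error(overlap_block_sets(CS, c("y", "z")), class = "NotACluster")
})

test_that("partition and disjointness invariants of the overlap-block sets", {
  for (seed in 1:15) {
    CS <- gen_closed_L_system(seed)
    all_b0 <- list()
    for (C in CS$clusters) {
      obs <- overlap_block_sets(CS, C)
      # D(C), Dbar(C) and {C} partition the system
      nk <- length(obs$d) + length(obs$dbar) + 1L
      expect_identical(nk, length(CS$clusters))
      if (length(obs$b0) > 0L) {
        expect_true(all(C %in% obs$u_set))
        expect_true(all(obs$u_set %in% obs$top))
        expect_true(phyclus:::cs_has(CS, obs$top))
        # bcal is the inclusion interval [C, Top(C)]
        interval <- Filter(function(D) all(C %in% D) && all(D %in% obs$top),
                           CS$clusters)
        expect_setequal(vapply(obs$bcal, phyclus:::cl_key, character(1)),
                        vapply(interval, phyclus:::cl_key, character(1)))
        all_b0[[length(all_b0) + 1L]] <- vapply(obs$b0, phyclus:::cl_key,
                                                character(1))
      }
    }
    # b0 sets of distinct clusters are pairwise disjoint
    expect_identical(anyDuplicated(unlist(all_b0)), 0L)
  }
})

test_that("blocks of the Hasse diagram are recoverable from the clusters", {
  fx <- fixtures()
  CS <- clustering_system(fx$F_D1)
  blc <- level1_blocks_from_clusters(CS)
  nt <- Filter(function(b) length(b) > 2L, blc)
  expect_length(nt, 1L)
  expect_setequal(vapply(nt[[1L]], paste, character(1), collapse = "|"),
                  c("x", "x|y", "x|z", "x|y|z"))
  expect_error(level1_blocks_from_clusters(fx$F_CS12),
               class = "PreconditionViolated")
  # hierarchies have only trivial blocks
  CT <- clustering_system(fx$F_T3)
  expect_true(all(lengths(level1_blocks_from_clusters(CT)) == 2L))
  # vertex-set agreement with blocks(hasse(CS)) on random systems
  for (seed in 1:25) {
    CS <- gen_closed_L_system(seed)
    blc <- level1_blocks_from_clusters(CS)
    from_cl <- sort(vapply(blc, function(b)
      paste(sort(vapply(b, phyclus:::hasse_vertex_id, character(1))),
            collapse = ";"), character(1)))
    H <- hasse(CS)
    from_h <- sort(vapply(blocks(H), function(b)
      paste(sort(b$vertices), collapse = ";"), character(1)))
    expect_identical(from_cl, from_h)
  }
})

test_that("characterisations: level-1, galled, binary level-1 systems", {
  fx <- fixtures()
  CS <- clustering_system(fx$F_D1)
  expect_true(is_level1_system(CS))
  expect_true(is_galled_system(CS))
  expect_true(is_binary_l1_system(CS))
  expect_false(is_level1_system(fx$F_CS12))
  expect_false(is_level1_system(fx$F_CS11))  # not closed
  # round trip: systems of generated level-1 networks pass, and the witness
  # constructors return networks of the advertised class with the same system
  for (seed in 1:25) {
    N <- gen_l1(seed)
    CS <- clustering_system(N)
    expect_true(is_level1_system(CS))
    H <- hasse(CS)
    expect_lte(network_level(H), 1L)
    expect_true(structural_flags(H)$phylogenetic)
    expect_cs_equal(clustering_system(H), CS)
    if (is_galled_system(CS)) expect_true(is_galled_tree(H))
    if (is_binary_l1_system(CS)) {
      B <- cluster_network_of(CS)
      expect_true(structural_flags(B)$binary)
      expect_cs_equal(clustering_system(B), CS)
    }
  }
})

test_that("no phylogenetic shortcut-free level-1 non-tree has a hierarchy", {
  for (seed in 1:20) {
    N <- gen_l1(seed)
    if (length(phyclus:::nw_hybrids(N)) > 0L) {
      expect_false(cs_flags(clustering_system(N))$hierarchy)
    }
  }
})

test_that("level-1 compatibility is decided by property (L)", {
  fx <- fixtures()
  CSx <- clustsys(list("x", "y", "z", c("x", "y"), c("y", "z"), c("x", "y", "z")))
  r <- check_l1_compatibility(CSx)
  expect_true(r$compatible)
  expect_true(is_galled_tree(r$network))
  fl <- structural_flags(r$network)
  expect_true(fl$separated && fl$phylogenetic)
  expect_identical(network_level(r$network), 1L)
  expect_false(check_l1_compatibility(fx$F_CS12)$compatible)
  # a hierarchy is compatible and yields its tree
  CT <- clustering_system(fx$F_T3)
  rt <- check_l1_compatibility(CT)
  expect_true(rt$compatible)
  expect_true(!is.null(isomorphic(rt$network, fx$F_T3)))
  # CS is contained in the clusters of the witness, which are exactly I(CS)
  for (seed in 1:15) {
    CS <- gen_closed_L_system(seed)
    CS2 <- clustsys(CS$clusters[-which.max(lengths(CS$clusters) *
                                             (lengths(CS$clusters) < length(CS$X)))],
                    X = CS$X)
    r <- check_l1_compatibility(CS2)
    expect_true(r$compatible)
    expect_true(all(cs_keyset(CS2) %in% cs_keyset(clustering_system(r$network))))
    expect_cs_equal(clustering_system(r$network), intersection_closure(CS2))
  }
})

test_that("binary level-1 compatibility needs indegree-2 hybrids in the closure", {
  fx <- fixtures()
  CSx <- clustsys(list("x", "y", "z", c("x", "y"), c("y", "z"), c("x", "y", "z")))
  rb <- binary_l1_compatible(CSx)
  expect_true(rb$compatible)
  expect_true(structural_flags(rb$network)$binary)
  expect_true(all(cs_keyset(CSx) %in%
                    cs_keyset(clustering_system(rb$network))))
  expect_false(binary_l1_compatible(fx$F_CS12)$compatible)
  # star clusters on four taxa: compatible via caterpillar refinement
  CSstar <- clustsys(list("1", "2", "3", "4", c("1", "2", "3", "4")))
  rs <- binary_l1_compatible(CSstar)
  expect_true(rs$compatible)
  expect_true(structural_flags(rs$network)$binary)
  expect_true(all(cs_keyset(CSstar) %in%
                    cs_keyset(clustering_system(rs$network))))
  # a system with an indegree-3 hybrid in the Hasse diagram is rejected
  CS3 <- clustsys(list("a", "b", "c", "d",
                       c("a", "b"), c("a", "c"), c("a", "d"),
                       c("a", "b", "c", "d")))
  expect_true(cs_flags(CS3)$property_L)
  expect_false(binary_l1_compatible(CS3)$compatible)
})

test_that("resolve_to_binary refines while keeping the clusters it had", {
  star <- build_network(rbind(c("r", "1"), c("r", "2"), c("r", "3"), c("r", "4")))
  B <- resolve_to_binary(star)
  expect_true(structural_flags(B)$binary)
  expect_true(all(cs_keyset(clustering_system(star)) %in%
                    cs_keyset(clustering_system(B))))
  fx <- fixtures()
  expect_true(!is.null(isomorphic(resolve_to_binary(fx$F_D1), fx$F_D1)))
  expect_error(resolve_to_binary(fx$F_P1), class = "NotLevel1")
  ind3 <- build_network(rbind(c("r", "p1"), c("r", "p2"), c("r", "h"),
                              c("p1", "h"), c("p2", "h"), c("h", "x"),
                              c("p1", "a"), c("p2", "b")))
  expect_identical(network_level(ind3), 1L)
  expect_error(resolve_to_binary(ind3), class = "HybridIndegreeTooHigh")
  for (seed in 1:15) {
    N <- gen_l1(seed)
    B <- resolve_to_binary(N)
    expect_true(structural_flags(B)$binary)
    expect_lte(network_level(B), 1L)
    expect_true(all(cs_keyset(clustering_system(N)) %in%
                      cs_keyset(clustering_system(B))))
  }
})

test_that("least_resolved_level1 equals regularization and the Hasse diagram", {
  fx <- fixtures()
  expect_identical(length(least_resolved_level1(fx$F_SC)$vertices), 3L)
  expect_identical(length(least_resolved_level1(fx$F_D1)$vertices), 6L)
  for (seed in 1:10) {
    CS <- gen_closed_L_system(seed)
    H <- hasse(CS)
    expect_true(!is.null(isomorphic(least_resolved_level1(H), H)))
    N <- gen_l1(seed)
    expect_true(!is.null(isomorphic(least_resolved_level1(N),
                                    hasse(clustering_system(N)))))
  }
  expect_error(least_resolved_level1(gen_star_bipartite(3, 2)), class = "NotLevel1")
})

test_that("children-cluster overlap at v marks exactly the cycle maxima", {
  for (seed in 1:12) {
    N <- least_resolved_level1(gen_l1(seed))
    maxima <- vapply(Filter(function(b) b$nontrivial, blocks(N)),
                     `[[`, character(1), "max_vertex")
    for (v in setdiff(N$vertices, N$leaves)) {
      kids <- phyclus:::nw_children(N, v)
      ovl <- FALSE
      if (length(kids) >= 2L) {
        for (i in seq_len(length(kids) - 1L)) for (j in (i + 1L):length(kids)) {
          if (length(intersect(cluster_of(N, kids[i]),
                               cluster_of(N, kids[j]))) > 0L) ovl <- TRUE
        }
      }
      expect_identical(ovl, v %in% maxima)
    }
  }
})
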