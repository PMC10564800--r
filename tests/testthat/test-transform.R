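test_that("expd preserves clusters, order, shortcut-freeness and level", {
  fx <- fixtures()
  for (seed in 1:12) {
    N <- gen_l1(seed)
    set.seed(seed)
    w <- sample(N$vertices, 1L)
    E <- expd(N, w)
    expect_identical(length(E$vertices), length(N$vertices) + 1L)
    expect_cs_equal(clustering_system(E), clustering_system(N))
    expect_identical(nrow(shortcuts(E)), nrow(shortcuts(N)))
    expect_identical(network_level(E), network_level(N))
    # ancestor relation on old vertices untouched
    r1 <- phyclus:::nw_reach(N); r2 <- phyclus:::nw_reach(E)
    expect_identical(r1, r2[N$vertices, N$vertices])
  }
  # phylogenetic is kept iff the expanded vertex is hybrid with outdeg != 1
  E <- expd(fx$F_T3, "1")
  expect_false(structural_flags(E)$phylogenetic)
  E <- expd(fx$F_T3, "r")
  expect_identical(E$root, "r__exp1")
})

test_that("cntr deletes the upper vertex and refuses shortcuts", {
  fx <- fixtures()
  B <- cntr(expd(fx$F_D1, "h"), c("h__exp1", "h"))
  expect_true(!is.null(isomorphic(B, fx$F_D1)))
  expect_error(cntr(fx$F_SC, c("r", "h")), class = "ShortcutContraction")
  Ct <- cntr(fx$F_T3, c("r", "a"))
  expect_identical(Ct$root, "a")
  expect_setequal(phyclus:::nw_children(Ct, "a"), c("1", "2", "3"))
  # level never increases when contracting a non-shortcut arc
  for (seed in 1:12) {
    N <- gen_l1(seed)
    sc <- apply(shortcuts(N), 1L, paste, collapse = "\r")
    for (i in seq_len(nrow(N$edges))) {
      arc <- N$edges[i, ]
      if (paste(arc, collapse = "\r") %in% sc) next
      expect_lte(network_level(cntr(N, arc)), network_level(N))
    }
  }
})

test_that("phylo_reduce suppresses all superfluous vertices, keeping clusters", {
  chain <- build_network(rbind(c("r", "a"), c("a", "x")))
  P <- phylo_reduce(chain)
  expect_identical(P$vertices, "x")
  fx <- fixtures()
  expect_true(!is.null(isomorphic(phylo_reduce(fx$F_D1), fx$F_D1)))
  E <- expd(fx$F_T3, "1")
  expect_true(!is.null(isomorphic(cntr_star(E, c("1__exp1", "1")), fx$F_T3)))
  for (seed in 1:10) {
    N <- expd(gen_l1(seed), "i1")
    P <- phylo_reduce(N)
    expect_true(structural_flags(P)$phylogenetic)
    expect_cs_equal(clustering_system(P), clustering_system(N))
    expect_lte(network_level(P), network_level(N))
  }
})

test_that("shortcut removal keeps vertices, clusters and the ancestor order", {
  fx <- fixtures()
  R <- remove_shortcut(fx$F_SC, c("r", "h"))
  expect_identical(sort(R$vertices), sort(fx$F_SC$vertices))
  for (v in R$vertices)
    expect_identical(cluster_of(R, v), cluster_of(fx$F_SC, v))
  expect_identical(nrow(shortcuts(R)), 0L)
  expect_error(remove_shortcut(fx$F_D1, fx$F_D1$edges[1L, ]),
               class = "NotAShortcut")
})

test_that("hasse builds the unique regular network of a clustering system", {
  fx <- fixtures()
  H <- hasse(fx$F_CSA)
  expect_identical(length(H$vertices), 3L)
  expect_true(!is.null(isomorphic(hasse(clustering_system(fx$F_T3)), fx$F_T3)))
  H12 <- hasse(fx$F_CS12)
  expect_identical(length(H12$vertices), 10L)
  expect_setequal(phyclus:::nw_hybrids(H12), c("x", "y", "z", "v"))
  for (seed in 1:15) {
    CS <- gen_closed_L_system(seed)
    H <- hasse(CS)
    expect_cs_equal(clustering_system(H), CS)
    r <- classify_regularity(H)
    expect_true(r$regular)
    expect_false(any(phyclus:::nw_outdeg(H) == 1L))
  }
})

test_that("regularize reaches hasse(C_N) independent of operation order", {
  fx <- fixtures()
  R <- regularize(fx$F_D1)
  expect_identical(length(R$vertices), 6L)
  expect_true(!is.null(isomorphic(R, hasse(clustering_system(fx$F_D1)))))
  R <- regularize(fx$F_SC, check = FALSE)
  expect_identical(length(R$vertices), 3L)
  expect_identical(leaf_set(R), c("x", "y"))
  expect_error(regularize(fixtures()$F_P1), class = "PccViolation")
  for (seed in 1:12) {
    N <- gen_l1(seed)
    H <- hasse(clustering_system(N))
    expect_true(!is.null(isomorphic(regularize(N), H)))
    expect_true(!is.null(isomorphic(regularize(H), H)))  # fixpoint
    # alternative order: contract outdeg-1 arcs before looking for shortcuts
    M <- N
    repeat {
      o1 <- names(which(phyclus:::nw_outdeg(M) == 1L))
      o1 <- Filter(function(u) !is_shortcut(M, c(u, phyclus:::nw_children(M, u))),
                   o1)
      if (length(o1) > 0L) {
        M <- cntr(M, c(o1[[1L]], phyclus:::nw_children(M, o1[[1L]])))
        next
      }
      sc <- shortcuts(M)
      if (nrow(sc) > 0L) { M <- remove_shortcut(M, sc[1L, ]); next }
      break
    }
    expect_true(!is.null(isomorphic(M, H)))
  }
})

test_that("cluster_network_of is the unique separated phylogenetic witness", {
  fx <- fixtures()
  expect_true(!is.null(isomorphic(cluster_network_of(fx$F_CSA), hasse(fx$F_CSA))))
  CN <- cluster_network_of(clustering_system(fx$F_D1))
  expect_true(!is.null(isomorphic(CN, fx$F_D1)))
  for (seed in 1:12) {
    CS <- gen_closed_L_system(seed)
    CN <- cluster_network_of(CS)
    r <- classify_regularity(CN)
    fl <- structural_flags(CN)
    expect_true(r$semi_regular && fl$separated && fl$phylogenetic)
    expect_cs_equal(clustering_system(CN), CS)
    # any other separated phylogenetic shortcut-free level-1 witness is
    # isomorphic to it: the generator's networks qualify after separation
    N <- gen_l1(seed)
    if (structural_flags(N)$separated && nrow(shortcuts(N)) == 0L &&
        structural_flags(N)$phylogenetic) {
      expect_true(!is.null(isomorphic(cluster_network_of(clustering_system(N)), N)))
    }
  }
})

test_that("hasse output is least-resolved: any rewrite changes the clusters", {
  for (seed in 1:8) {
    H <- hasse(gen_closed_L_system(seed))
    expect_identical(nrow(shortcuts(H)), 0L)
    for (i in seq_len(nrow(H$edges))) {
      M <- cntr(H, H$edges[i, ])
      expect_false(phyclus:::cs_equal(clustering_system(M), clustering_system(H)))
    }
  }
})

test_that("isomorphism finds witnesses and respects leaf fixing", {
  fx <- fixtures()
  id <- isomorphic(fx$F_D1, fx$F_D1)
  expect_identical(unname(id), names(id))
  # subdividing an arc changes the graph but not the clusters
  sub <- build_network(rbind(c("r", "u"), c("r", "v"), c("u", "y"), c("v", "z"),
                             c("u", "h"), c("v", "h"), c("h", "m"), c("m", "x")))
  expect_null(isomorphic(fx$F_D1, sub))
  expect_cs_equal(clustering_system(fx$F_D1), clustering_system(sub))
  # relabelled copies: graph-isomorphic but not leaf-fixing isomorphic
  swapped <- build_network(fx$F_D1$edges,
                           leaf_labels = c(x = "y", y = "x", z = "z"))
  expect_null(isomorphic(fx$F_D1, swapped, fix_leaves = TRUE))
  expect_false(is.null(isomorphic(fx$F_D1, swapped, fix_leaves = FALSE)))
  # witness correctness on shuffled copies of generated networks
  for (seed in 1:10) {
    N <- gen_l1(seed)
    set.seed(seed)
    perm <- stats::setNames(paste0("w", sample(seq_along(N$vertices))), N$vertices)
    perm[N$leaves] <- N$leaves
    e2 <- cbind(perm[N$edges[, 1L]], perm[N$edges[, 2L]])
    N2 <- build_network(e2[sample(nrow(e2)), , drop = FALSE])
    phi <- isomorphic(N, N2)
    expect_false(is.null(phi))
    for (i in seq_len(nrow(N$edges))) {
      expect_true(phyclus:::nw_has_arc(N2, phi[[N$edges[i, 1L]]],
                                       phi[[N$edges[i, 2L]]]))
    }
  }
})

test_that("phi_pcc maps positionally and is an isomorphism for semi-regular nets", {
  fx <- fixtures()
  phi <- phi_pcc(fx$F_D1, fx$F_D1)
  expect_identical(unname(phi), names(phi))
  expect_error(phi_pcc(fx$F_P1, fx$F_P1), class = "PccViolation")
  expect_error(phi_pcc(fx$F_D1, fx$F_T3), class = "MultisetMismatch")
  for (seed in 1:30) {
    N <- gen_l1(seed)
    # independently rebuilt copy: new vertex ids, shuffled arcs
    set.seed(seed + 1000L)
    perm <- stats::setNames(paste0("z", sample(seq_along(N$vertices))), N$vertices)
    perm[N$leaves] <- N$leaves
    e2 <- cbind(perm[N$edges[, 1L]], perm[N$edges[, 2L]])
    N2 <- build_network(e2[sample(nrow(e2)), , drop = FALSE])
    phi <- phi_pcc(N, N2)
    # leaf-fixing
    expect_identical(phi[N$leaves], stats::setNames(N$leaves, N$leaves))
    # cluster-preserving
    for (v in N$vertices)
      expect_identical(cluster_of(N, v), cluster_of(N2, phi[[v]]))
    # graph isomorphism (semi-regular networks are encoded by multisets)
    for (i in seq_len(nrow(N$edges))) {
      expect_true(phyclus:::nw_has_arc(N2, phi[[N$edges[i, 1L]]],
                                       phi[[N$edges[i, 2L]]]))
    }
  }
})

test_that("pairwise lcas survive contraction of a tree arc as stated", {
  tested <- 0L
  for (seed in 1:8) {
    N <- gen_l1(seed, n = 7L, blocks = 1L)
    ind <- phyclus:::nw_indeg(N); outd <- phyclus:::nw_outdeg(N)
    X <- leaf_set(N)
    for (i in seq_len(nrow(N$edges))) {
      vp <- unname(N$edges[i, 1L]); v <- unname(N$edges[i, 2L])
      if (ind[[v]] > 1L || outd[[v]] == 0L) next
      tested <- tested + 1L
      M <- cntr(N, c(vp, v))
      for (a in seq_along(X)) for (b in a:length(X)) {
        l1 <- lca_set(N, c(X[a], X[b]))$lca_set
        l2 <- lca_set(M, c(X[a], X[b]))$lca_set
        expect_identical(l2, if (identical(l1, vp)) v else l1)
      }
    }
  }
  expect_gt(tested, 10L)
})
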