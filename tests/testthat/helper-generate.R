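# Shared generation helpers.  Configurations are always feasible: the number
# of cycle blocks requested scales with the number of taxa, and a handful of
# retry seeds absorbs the rare tree shape without enough fat vertices.

gen_l1 <- function(seed, n = NULL, blocks = NULL, ...) {
  if (is.null(n)) n <- 4L + (seed %% 6L)
  if (is.null(blocks)) blocks <- min(seed %% 3L, max(0L, (n - 3L) %/% 3L))
  for (off in 0:9) {
    cfg <- generator_config(n, blocks, max_block_size = 6L,
                            seed = seed + 7919L * off, ...)
    N <- tryCatch(gen_random_level1(cfg), InfeasibleConfig = function(e) NULL)
    if (!is.null(N)) return(N)
    blocks <- max(0L, blocks - 1L)
  }
  stop("could not generate a feasible level-1 network")
}

# a random closed clustering system satisfying (L): the cluster system of a
# random level-1 network
gen_closed_L_system <- function(seed, ...) clustering_system(gen_l1(seed, ...))

expect_cs_equal <- function(A, B) {
  expect_true(phyclus:::cs_equal(A, B))
}

cs_keyset <- function(CS) vapply(CS$clusters, function(C) paste(C, collapse = "|"),
                                 character(1))

with_seed_local <- function(seed, code) phyclus:::with_seed(seed, code)
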