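# Markov clustering, the stochastic matrix, silhouette scoring, and the
# refinement orchestration.

cfg <- resl_config()

# dist_graph literal for exact-weight tests
make_graph <- function(ids, edges, cutoff = 0.044) {
  structure(list(ids = sort(ids), edges = edges, cutoff = cutoff,
                 min_overlap = 300L), class = "dist_graph")
}

test_that("init_stochastic normalizes threshold-scaled similarities", {
  # two nodes at d = 0: every column is (0.5, 0.5)
  g <- make_graph(c("a", "b"),
                  data.frame(a = "a", b = "b", mism = 0L, sites = 600L,
                             d = 0))
  sm <- init_stochastic(c("a", "b"), g, cfg)
  expect_equal(unname(sm$M), matrix(0.5, 2, 2))
  expect_equal(colSums(sm$M), c(a = 1, b = 1))

  # single node: 1x1 identity
  g1 <- make_graph("a", data.frame(a = character(), b = character(),
                                   mism = integer(), sites = integer(),
                                   d = numeric()))
  expect_equal(unname(init_stochastic("a", g1, cfg)$M),
               matrix(1, 1, 1))

  # three nodes with distinct distances: hand normalization of
  # w = 1 - d/t with unit self-loops
  e <- data.frame(a = c("a", "a", "b"), b = c("b", "c", "c"),
                  mism = c(5L, 10L, 20L), sites = 1000L,
                  d = c(0.005, 0.010, 0.020))
  sm3 <- init_stochastic(c("a", "b", "c"), make_graph(c("a", "b", "c"), e),
                         cfg)
  w_ab <- 1 - 0.005 / 0.022
  w_ac <- 1 - 0.010 / 0.022
  w_bc <- 1 - 0.020 / 0.022
  col_a <- c(1, w_ab, w_ac) / (1 + w_ab + w_ac)
  expect_equal(unname(sm3$M[, "a"]), col_a, tolerance = 1e-12)
  expect_equal(unname(colSums(sm3$M)), rep(1, 3), tolerance = 1e-12)
})

test_that("column stochasticity is preserved through the iteration", {
  for (seed in 70:74) {
    sm <- random_stoch_matrix(sample(5:15, 1), seed)
    M <- sm$M
    for (i in 1:5) {
      M <- M %*% M
      M <- sweep(M^1.6, 2, colSums(M^1.6), "/")
      expect_equal(unname(colSums(M)), rep(1, ncol(M)), tolerance = 1e-9)
    }
    p <- mcl(sm, r = 1.6)
    expect_setequal(names(p), sm$node_ids)
  }
})

test_that("disconnected components never mix, connected groups unify at r = 1", {
  ids <- sprintf("n%02d", 1:6)
  W <- matrix(0, 6, 6, dimnames = list(ids, ids))
  W[1:3, 1:3] <- 0.9
  W[4:6, 4:6] <- 0.8
  diag(W) <- 1
  sm <- structure(list(node_ids = ids,
                       M = sweep(W, 2, colSums(W), "/")),
                  class = "stoch_matrix")
  for (r in c(1.0, 1.4, 2.0, 2.4)) {
    p <- mcl(sm, r)
    expect_equal(n_clusters(p), 2L, label = paste("r =", r))
    expect_equal(length(unique(unclass(p)[ids[1:3]])), 1L)
    expect_equal(length(unique(unclass(p)[ids[4:6]])), 1L)
  }
  # connected group at r = 1: inflation is the identity and repeated
  # squaring converges to the rank-one stationary matrix -> one cluster
  W[3, 4] <- W[4, 3] <- 0.5
  smc <- structure(list(node_ids = ids,
                        M = sweep(W, 2, colSums(W), "/")),
                   class = "stoch_matrix")
  expect_equal(n_clusters(mcl(smc, 1.0)), 1L)
})

test_that("a light bridge between two cliques is cut at r = 2", {
  ids <- sprintf("n%02d", 1:6)
  W <- matrix(0, 6, 6, dimnames = list(ids, ids))
  W[1:3, 1:3] <- 0.95
  W[4:6, 4:6] <- 0.95
  W[3, 4] <- W[4, 3] <- 0.1
  diag(W) <- 1
  sm <- structure(list(node_ids = ids,
                       M = sweep(W, 2, colSums(W), "/")),
                  class = "stoch_matrix")
  p <- mcl(sm, 2.0)
  expect_equal(n_clusters(p), 2L)
  expect_equal(length(unique(unclass(p)[ids[1:3]])), 1L)
  expect_equal(length(unique(unclass(p)[ids[4:6]])), 1L)
})

test_that("mcl agrees with an independent numpy implementation", {
  for (seed in 80:87) {
    sm <- random_stoch_matrix(sample(6:20, 1), seed)
    for (r in c(1.2, 1.6, 2.0)) {
      ref <- oracle_mcl_py(sm$M, r)
      ref_part <- new_partition(stats::setNames(as.character(ref),
                                                sm$node_ids))
      expect_true(same_partition(mcl(sm, r), ref_part),
                  label = sprintf("seed %d r %.1f", seed, r))
    }
  }
})

test_that("silhouette_index matches hand computation and conventions", {
  ids <- c("a", "b", "c", "d")
  d <- matrix(0, 4, 4, dimnames = list(ids, ids))
  d["a", "b"] <- d["b", "a"] <- 0.2
  d["c", "d"] <- d["d", "c"] <- 0.4
  d["a", "c"] <- d["c", "a"] <- 0.6
  d["a", "d"] <- d["d", "a"] <- 0.8
  d["b", "c"] <- d["c", "b"] <- 0.5
  d["b", "d"] <- d["d", "b"] <- 0.7
  p <- new_partition(c(a = "1", b = "1", c = "2", d = "2"))
  # per-point scores computed by hand from (b - a)/max(a, b)
  hand <- mean(c(0.5 / 0.7, 0.4 / 0.6, 0.15 / 0.55, 0.35 / 0.75))
  expect_equal(silhouette_index(p, d), hand, tolerance = 1e-12)

  # perfect separation limit and the single-cluster convention
  d2 <- matrix(0.05, 4, 4, dimnames = list(ids, ids))
  d2[1:2, 1:2] <- 0; d2[3:4, 3:4] <- 0
  expect_equal(silhouette_index(p, d2), 1.0)
  expect_equal(silhouette_index(new_partition(
    stats::setNames(rep("x", 4), ids)), d), 0)
})

test_that("silhouette_index agrees with cluster::silhouette", {
  skip_if_not_installed("cluster")
  set.seed(90)
  for (i in 1:5) {
    n <- sample(6:12, 1)
    pts <- matrix(stats::rnorm(2 * n), ncol = 2)
    d <- as.matrix(stats::dist(pts))
    ids <- sprintf("p%02d", seq_len(n))
    dimnames(d) <- list(ids, ids)
    k <- sample(2:3, 1)
    cl <- stats::kmeans(pts, k)$cluster
    # compare only when no singleton clusters (conventions differ there)
    if (min(table(cl)) < 2) next
    ref <- mean(cluster::silhouette(cl, stats::dist(pts))[, "sil_width"])
    p <- new_partition(stats::setNames(as.character(cl), ids))
    expect_equal(silhouette_index(p, d), ref, tolerance = 1e-9)
  }
})

test_that("refinement group selection follows the eligibility rules", {
  sim <- simulate_barcodes(sim_spec(n_species = 6, seqs_per_species = 4,
                                    seed = 91))
  recs <- sim$records
  # make one species monomorphic and one a pair
  first <- which(recs$species == sort(unique(recs$species))[1])
  recs$seq[first] <- recs$seq[first[1]]
  keep <- setdiff(seq_len(nrow(recs)),
                  which(recs$species == sort(unique(recs$species))[2])[1:2])
  recs <- recs[keep, ]
  part <- slc_streaming(recs, t = 0.022)
  graph <- build_dist_graph(recs, 0.044)
  groups <- select_refinement_groups(part, graph, cfg)
  flat <- unlist(groups)
  expect_false(any(recs$id[recs$species == sort(unique(recs$species))[1]]
                   %in% flat))        # no variation
  expect_false(any(recs$id[recs$species == sort(unique(recs$species))[2]]
                   %in% flat))        # two members
  expect_equal(anyDuplicated(flat), 0L)
})

test_that("near-threshold OTUs are collapsed into one refinement group", {
  base <- make_coding_seq(600, 92)
  # two tight trios 3% apart: distinct SLC clusters at t=2.2%, one group
  other <- substitute_bases(base, 1:18)
  recs <- seq_records(
    sprintf("s%d", 1:6),
    c(base, substitute_bases(base, 1), substitute_bases(base, 2),
      other, substitute_bases(other, 30), substitute_bases(other, 31)))
  part <- slc_streaming(recs, t = 0.022)
  expect_equal(n_clusters(part), 2L)
  groups <- select_refinement_groups(part, build_dist_graph(recs, 0.044),
                                     cfg)
  expect_equal(length(groups), 1L)
  expect_setequal(groups[[1]], recs$id)
})

test_that("refinement splits gapped subclusters but not continua", {
  # two haplotype clouds 1.5% apart, each <= 0.3% wide: SLC merges them
  # at t = 2.2%, refinement must recover the two clouds
  sim <- simulate_barcodes(sim_spec(n_species = 5, seqs_per_species = 10,
                                    seed = 93))
  gap <- inject_structure(sim, "GAPPED_SUBCLUSTERS", species = 1)
  slc <- slc_streaming(gap$records, t = 0.022)
  expect_equal(n_clusters(slc), 5L)
  refined <- resl_refine(slc, gap$records, cfg)
  expect_equal(n_clusters(refined), 6L)

  # a chain continuum (no discontinuity) stays one OTU despite its
  # diameter approaching the threshold
  base <- make_coding_seq(658, 94)
  seqs <- Reduce(function(s, i) substitute_bases(s, (2 * i - 1):(2 * i)),
                 1:9, accumulate = TRUE, init = base)
  chain <- seq_records(sprintf("c%02d", 1:10), seqs)
  pc <- slc_streaming(chain, t = 0.022)
  expect_equal(n_clusters(pc), 1L)
  expect_equal(n_clusters(resl_refine(pc, chain, cfg)), 1L)
})

test_that("resl_refine passes unselected OTUs through unchanged", {
  base <- make_coding_seq(600, 95)
  recs <- seq_records(c("a", "b", "c"),
                      c(base, base, substitute_bases(base, 1:60)))
  part <- slc_streaming(recs, t = 0.022)
  refined <- resl_refine(part, recs, cfg)
  expect_true(same_partition(part, refined))
})

test_that("refinement never merges nodes across refinement groups", {
  for (seed in 96:98) {
    sim <- random_sim_instance(seed)
    part <- slc_streaming(sim$records, t = 0.022)
    graph <- build_dist_graph(sim$records, 0.044)
    groups <- select_refinement_groups(part, graph, cfg)
    refined <- resl_refine(part, sim$records, cfg, graph = graph)
    grp_of <- stats::setNames(rep(seq_along(groups), lengths(groups)),
                              unlist(groups))
    for (members in partition_members(refined)) {
      gs <- unique(grp_of[members])
      gs <- gs[!is.na(gs)]
      expect_true(length(gs) <= 1L)
    }
  }
})
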