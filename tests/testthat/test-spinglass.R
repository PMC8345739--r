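quick_cfg <- annealing_config(restarts = 10, seeds = 1:10,
                              sweeps_per_temp = 10, cooling = 0.95)

two_cliques <- function() {
  W <- matrix(0, 10, 10, dimnames = list(letters[1:10], letters[1:10]))
  W[1:5, 1:5] <- 1; W[6:10, 6:10] <- 1; diag(W) <- 0
  W
}

test_that("all-singleton partitions have zero energy and labels permute freely", {
  W <- random_signed_graph(7, 0.6)
  g <- graph_from_w(W)
  expect_equal(partition_quality(g, 1:7), 0)
  set.seed(2)
  a <- sample(1:3, 7, replace = TRUE)
  perm <- c(3, 1, 2)
  expect_equal(partition_quality(g, a), partition_quality(g, perm[a]))
})

test_that("triangle clique energy matches hand arithmetic", {
  W <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(W) <- 0
  g <- graph_from_w(W)
  # strengths s_i = 2, m = 3 edges weight 1 => p_ij = 4/6; per edge w - p = 1/3
  expect_equal(partition_quality(g, c(1, 1, 1)), -3 * (1 - 4 / 6))
})

test_that("disconnected positive cliques split; complete graphs stay whole", {
  g <- graph_from_w(two_cliques())
  part <- anneal_partition(g, quick_cfg, seed = 4)
  expect_equal(part$n_communities, 2)
  expect_length(unique(part$assignment[1:5]), 1)
  expect_length(unique(part$assignment[6:10]), 1)
  K <- matrix(1, 8, 8, dimnames = list(letters[1:8], letters[1:8])); diag(K) <- 0
  expect_equal(anneal_partition(graph_from_w(K), quick_cfg, 1)$n_communities, 1)
})

test_that("annealer is deterministic given a seed and reports its own energy", {
  W <- random_signed_graph(10, 0.5)
  g <- graph_from_w(W)
  p1 <- anneal_partition(g, quick_cfg, seed = 7)
  p2 <- anneal_partition(g, quick_cfg, seed = 7)
  expect_identical(p1$assignment, p2$assignment)
  expect_identical(p1$hamiltonian, p2$hamiltonian)
  expect_equal(partition_quality(g, p1$assignment, quick_cfg),
               p1$hamiltonian, tolerance = 1e-10)
  # never worse than the trivial all-singleton state
  expect_lte(p1$hamiltonian, 0)
})

test_that("annealed energy matches the exhaustive minimum on small graphs", {
  set.seed(55)
  misses <- 0
  for (i in 1:12) {
    W <- random_signed_graph(6, 0.6)
    g <- graph_from_w(W)
    if (igraph::ecount(g) == 0) next
    hmin <- exhaustive_min_energy(W)
    got <- consensus_partition(g, quick_cfg)$hamiltonian
    expect_gte(got, hmin - 1e-9)
    if (got > hmin + 1e-9) misses <- misses + 1
  }
  expect_lte(misses, 1)
})

test_that("raising the resolution never merges communities on positive graphs", {
  g <- graph_from_w(two_cliques())
  ns <- vapply(c(0.5, 1, 2, 4), function(gam) {
    cfg <- annealing_config(gamma_pos = gam, gamma_neg = gam, restarts = 6,
                            seeds = 1:6, sweeps_per_temp = 10, cooling = 0.95)
    consensus_partition(g, cfg)$n_communities
  }, numeric(1))
  expect_true(all(diff(ns) >= 0))
})

test_that("consensus on a deterministic toy is perfectly stable", {
  g <- graph_from_w(two_cliques())
  cfg <- annealing_config(restarts = 6, seeds = 1:6, sweeps_per_temp = 10,
                          cooling = 0.95)
  part <- consensus_partition(g, cfg)
  expect_true(all(part$stability %in% c(0, 1)))
  expect_equal(part$n_communities, 2)
})

test_that("planted four-block signed networks are recovered across restarts", {
  blocks <- rep(1:4, each = 4)
  W <- outer(blocks, blocks, function(a, b) ifelse(a == b, 0.8, -0.4))
  diag(W) <- 0
  dimnames(W) <- list(paste0("m", 1:16), paste0("m", 1:16))
  g <- graph_from_w(W)
  hits <- 0
  for (s in 1:100) {
    part <- anneal_partition(g, annealing_config(restarts = 1, seeds = 1,
                                                 sweeps_per_temp = 10,
                                                 cooling = 0.95), seed = s)
    if (part$n_communities == 4 &&
        all(tapply(part$assignment, blocks, function(v)
          length(unique(v))) == 1))
      hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("edgeless networks fall back to singletons with a warning", {
  g <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g)$name <- c("a", "b", "c")
  expect_warning(part <- anneal_partition(g, quick_cfg, 1), "edgeless")
  expect_equal(part$n_communities, 3)
  expect_equal(part$hamiltonian, 0)
})

test_that("weighted partition of the fixture network agrees with an
           independent spin-glass implementation", {
  fx <- table2_correlations()
  p <- ifelse(fx$significant, 0.01, 0.5)
  net <- build_significance_network(fx$rho, p)
  cfg <- annealing_config(restarts = 20, seeds = 1:20)
  ours <- consensus_partition(net, cfg)
  set.seed(1)
  ref <- igraph::cluster_spinglass(net, spins = 25, gamma = 1,
                                   implementation = "neg", gamma.minus = 1)
  expect_equal(ours$n_communities, length(ref))
  # same partition up to label permutation
  expect_equal(length(unique(paste(ours$assignment,
                                   igraph::membership(ref)))),
               ours$n_communities)
})
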