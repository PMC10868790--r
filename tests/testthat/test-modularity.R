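test_that("modularity score matches hand-derived closed forms", {
  # two disconnected unit-weight dyads under their true partition
  expect_equal(modularity_score(two_dyads(), c(1, 1, 2, 2), gamma = 1), 0.5)
  # all nodes in one module: configuration-null totals cancel
  expect_equal(modularity_score(two_dyads(), rep(1, 4), gamma = 1), 0)
  expect_error(modularity_score(matrix(0, 3, 3), c(1, 2, 3)), "empty graph")
})

test_that("modularity is affine decreasing in the resolution", {
  w <- random_weighted_graph(12, 0.4, seed = 2)
  part <- rep(1:3, each = 4)
  gammas <- c(0.5, 1, 2, 4)
  qs <- sapply(gammas, function(g) modularity_score(w, part, g))
  expect_true(all(diff(qs) < 0))
})

test_that("modularity agrees with the igraph implementation at gamma = 1", {
  for (s in 1:5) {
    w <- random_weighted_graph(15, 0.3, seed = s)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    part <- sample(1:3, 15, replace = TRUE)
    expect_equal(modularity_score(w, part, 1),
                 igraph::modularity(g, part, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("Louvain recovers the optimum found by exhaustive search", {
  w <- two_cliques(4)
  p <- optimize_partition(w, gamma = 1, seed = 1, n_restarts = 5)
  # brute force over all 4140 partitions of 8 nodes
  best_q <- -Inf
  best_lab <- NULL
  for (part in all_partitions(8)) {
    lab <- blocks_to_labels(part, 8)
    q <- modularity_score(w, lab, 1)
    if (q > best_q) { best_q <- q; best_lab <- lab }
  }
  expect_equal(p$q, best_q, tolerance = 1e-12)
  expect_equal(adjusted_rand_index(p$sigma, best_lab), 1)
  expect_equal(adjusted_rand_index(p$sigma, rep(1:2, each = 4)), 1)
})

test_that("optimization is deterministic and never below trivial baselines", {
  w <- random_weighted_graph(20, 0.2, seed = 7)
  p1 <- optimize_partition(w, gamma = 1.3, seed = 42)
  p2 <- optimize_partition(w, gamma = 1.3, seed = 42)
  expect_identical(p1$sigma, p2$sigma)
  expect_gte(p1$q, modularity_score(w, seq_len(20), 1.3))
  expect_gte(p1$q, modularity_score(w, rep(1, 20), 1.3))
})

test_that("disconnected components are never merged", {
  p <- optimize_partition(two_dyads(), gamma = 1, seed = 1)
  expect_equal(p$n_modules, 2)
  expect_equal(adjusted_rand_index(p$sigma, c(1, 1, 2, 2)), 1)
})

test_that("multiresolution ensemble respects grid and module-count window", {
  sbm <- sbm_graph(n = 48, k = 4, p_in = 0.5, p_out = 0.05, seed = 3)
  ens <- mrcc_ensemble(sbm$weights, n_gamma = 60, seed = 3)
  expect_lte(length(ens$partitions), 60)
  n_mod <- sapply(ens$partitions, `[[`, "n_modules")
  expect_true(all(n_mod >= 2 & n_mod <= 24))
  # log-spaced grid: consecutive ratios constant
  ratios <- ens$gamma_grid[-1] / ens$gamma_grid[-length(ens$gamma_grid)]
  expect_lt(diff(range(ratios)), 1e-12)
  # planted partition appears in the ensemble at some resolution
  aris <- sapply(ens$partitions, function(p) {
    adjusted_rand_index(p$sigma, sbm$blocks)
  })
  expect_equal(max(aris), 1)
})

test_that("ensemble errors when no resolution separates modules", {
  w <- matrix(1, 6, 6); diag(w) <- 0
  expect_error(mrcc_ensemble(w, n_gamma = 10, coarse_range = c(1e-4, 1e-3)),
               "widen")
})

test_that("co-classification matrix counts co-assignments", {
  p1 <- structure(list(sigma = c(1L, 1L, 2L), gamma = 1, q = 0,
                       n_modules = 2L), class = "partition")
  p2 <- structure(list(sigma = c(1L, 2L, 2L), gamma = 1, q = 0,
                       n_modules = 2L), class = "partition")
  cc <- coclassification_matrix(list(p1, p2))
  expect_equal(cc[1, 2], 0.5)
  expect_equal(cc[2, 3], 0.5)
  expect_equal(cc[1, 3], 0)
  expect_equal(diag(cc), rep(1, 3))
  expect_identical(cc, t(cc))
  # identical partitions -> 0/1 block matrix
  cc2 <- coclassification_matrix(list(p1, p1))
  expect_true(all(cc2 %in% c(0, 1)))
})

test_that("consensus of a block CC reproduces the blocks", {
  sigma <- rep(1:3, times = c(4, 3, 3))
  cc <- outer(sigma, sigma, function(a, b) as.numeric(a == b))
  cons <- consensus_from_cc(cc, seed = 2, n_restarts = 10)
  expect_equal(adjusted_rand_index(cons$sigma, sigma), 1)
})

test_that("consensus is invariant under node relabeling", {
  sbm <- sbm_graph(n = 40, k = 3, p_in = 0.6, p_out = 0.05, seed = 8)
  ens <- mrcc_ensemble(sbm$weights, n_gamma = 40, seed = 8)
  cc <- coclassification_matrix(ens)
  cons <- consensus_from_cc(cc, seed = 1, n_restarts = 20)
  perm <- sample(40)
  cons_p <- consensus_from_cc(cc[perm, perm], seed = 1, n_restarts = 20)
  expect_equal(adjusted_rand_index(cons_p$sigma, cons$sigma[perm]), 1)
})

test_that("consensus ARI grows with block contrast", {
  contrasts <- c(0.1, 0.25, 0.5)
  aris <- sapply(contrasts, function(p_in) {
    vals <- sapply(1:5, function(s) {
      sbm <- sbm_graph(n = 40, k = 4, p_in = p_in, p_out = 0.05, seed = s)
      ens <- mrcc_ensemble(sbm$weights, n_gamma = 30, seed = s)
      cons <- consensus_from_cc(coclassification_matrix(ens),
                                seed = s, n_restarts = 20)
      adjusted_rand_index(cons$sigma, sbm$blocks)
    })
    mean(vals)
  })
  expect_true(all(diff(aris) >= 0))
})

test_that("partition features match hand-computed definitions", {
  # planted cliques of sizes 3 and 2, no extra edges -> IMD = 1
  w <- sym_from_edges(5, rbind(c(1, 2, 1), c(1, 3, 1), c(2, 3, 1), c(4, 5, 1)))
  xyz <- cbind(seq_len(5), 0, 0)
  ed <- as.matrix(dist(xyz))
  f <- partition_features(w, ed, c(1, 1, 1, 2, 2))
  expect_equal(f$imd, 1)

  # one module -> no between-module edges
  f1 <- partition_features(w, ed, rep(1, 5))
  expect_equal(f1$longdist_fraction, 0)

  expect_error(partition_features(w, ed, seq_len(5)), "singleton")
})

test_that("long-distance fraction counts top-5% bridges per definition", {
  # 20 edges: a 1D chain of 20 nodes (19 edges) + one very long bridge
  n <- 20
  edges <- cbind(seq_len(n - 1), 2:n, 1)
  w <- sym_from_edges(n, rbind(edges, c(1, n, 1)))
  xyz <- cbind(seq_len(n), 0, 0)
  ed <- as.matrix(dist(xyz))
  part <- rep(1:2, each = n / 2)
  f <- partition_features(w, ed, part)
  # top 5% of 20 edges = 1 edge = the (1, 20) bridge, which spans modules;
  # normalized by the 2 modules -> 0.5
  expect_equal(f$longdist_fraction, 0.5)
})

test_that("interhemispheric index hits its forced values", {
  hemi <- c("L", "L", "R", "R")
  # modules perfectly aligned with hemispheres
  cc_aligned <- outer(c(1, 1, 2, 2), c(1, 1, 2, 2),
                      function(a, b) as.numeric(a == b))
  expect_equal(interhemispheric_cc(cc_aligned, hemi), 0)
  # hemisphere-blind agreement
  cc_const <- matrix(0.7, 4, 4); diag(cc_const) <- 1
  expect_equal(interhemispheric_cc(cc_const, hemi), 1)
  # hand-set entries: inter pairs (1,3),(1,4),(2,3),(2,4); intra (1,2),(3,4)
  cc <- matrix(1, 4, 4)
  cc[1, 3] <- cc[3, 1] <- 0.2; cc[1, 4] <- cc[4, 1] <- 0.4
  cc[2, 3] <- cc[3, 2] <- 0.6; cc[2, 4] <- cc[4, 2] <- 0.8
  cc[1, 2] <- cc[2, 1] <- 0.9; cc[3, 4] <- cc[4, 3] <- 0.7
  expect_equal(interhemispheric_cc(cc, hemi), 0.5 / 0.8)
})
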