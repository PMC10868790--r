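test_that("portrait of a single edge occupies one distance bin", {
  p <- compute_portrait(k2(0.5))
  # only one distinct distance (2 = 1/0.5): both nodes have k = 1 there
  occupied <- which(rowSums(p$b[, -1, drop = FALSE]) > 0)
  expect_length(occupied, 1)
  expect_equal(p$b[occupied, 2], 2) # k = 1 column
})

test_that("path-graph portrait bins the hand-enumerated distance multiset", {
  # P3 distances per node: node1 {1,2}, node2 {1,1}, node3 {1,2}
  edges <- c(0, 1.5, 2.5)
  p <- compute_portrait(path3(), bin_edges = edges)
  # bin 1 = (0, 1.5]: node2 has k=2, nodes 1 and 3 have k=1
  expect_equal(p$b[1, 2], 2) # two nodes with k = 1
  expect_equal(p$b[1, 3], 1) # one node with k = 2
  # bin 2 = (1.5, 2.5]: nodes 1 and 3 have k=1, node 2 has k=0
  expect_equal(p$b[2, 2], 2)
  expect_equal(p$b[2, 1], 1)
  # invariant: sum_k k B[l,k] <= N (N-1)
  k <- 0:(ncol(p$b) - 1)
  expect_true(all(p$b %*% k <= 3 * 2))
})

test_that("portraits are deterministic and bin edges validated", {
  w <- random_weighted_graph(12, 0.4, seed = 1)
  e <- portrait_bin_edges(w)
  expect_identical(compute_portrait(w, e), compute_portrait(w, e))
  expect_error(compute_portrait(w, c(0, 2, 1)), "increasing")
})

test_that("portrait divergence is a bounded symmetric pseudometric", {
  set.seed(42)
  for (s in 1:20) {
    w1 <- random_weighted_graph(12, 0.3, seed = 2 * s)
    w2 <- random_weighted_graph(12, 0.4, seed = 2 * s + 1)
    e <- portrait_bin_edges(list(w1, w2))
    p1 <- compute_portrait(w1, e); p2 <- compute_portrait(w2, e)
    d12 <- portrait_divergence(p1, p2)
    expect_equal(portrait_divergence(p1, p1), 0)
    expect_equal(d12, portrait_divergence(p2, p1))
    expect_gte(d12, 0)
    expect_lte(d12, 1)
  }
})

test_that("divergence equals an independent JSD of hand-built portraits", {
  # K2 vs P3, unweighted, shared bins chosen by hand
  edges <- c(0, 1.5, 2.5)
  pa <- compute_portrait(k2(1), edges)
  pb <- compute_portrait(path3(), edges)
  # hand-built joint (l, k) mass grids over (l in 1:3, k in 0:3), entries
  # k * B[l,k]: K2 has both nodes with k=1 in bin 1; P3 has nodes 1,3 with
  # k=1 and node 2 with k=2 in bin 1, plus nodes 1,3 with k=1 in bin 2
  grid_a <- matrix(0, 3, 4); grid_a[1, 2] <- 1 * 2
  grid_b <- matrix(0, 3, 4); grid_b[1, 2] <- 1 * 2; grid_b[1, 3] <- 2 * 1
  grid_b[2, 2] <- 1 * 2
  oracle <- jsd_oracle(as.vector(grid_a / sum(grid_a)),
                       as.vector(grid_b / sum(grid_b)))
  expect_equal(portrait_divergence(pa, pb), oracle, tolerance = 1e-12)
})

test_that("portraits of disconnected graphs use the overflow bin", {
  e <- c(0, 1.5)
  p <- compute_portrait(two_dyads(), e)
  # each node: 1 neighbor at distance 1, 2 unreachable nodes
  expect_equal(p$b[1, 2], 4)        # all 4 nodes have k=1 in bin 1
  expect_equal(p$b[2, 3], 4)        # all 4 nodes have k=2 in overflow
})

test_that("representative selection returns the min-mean-distance instance", {
  b <- small_bundle(n_nodes = 30, volume = 5, seed = 3)
  inst <- jitter_replicates(b, n = 3, jitter_sd = 0.3, rewire_frac = 0.1,
                            seed = 2)
  sel <- select_representative(inst)
  # brute-force double loop over the same NPD matrix
  md <- sapply(seq_along(inst), function(i) {
    s <- 0
    for (j in seq_along(inst)) if (j != i) s <- s + sel$npd[i, j]
    s / (length(inst) - 1)
  })
  expect_equal(sel$mean_distance, md, tolerance = 1e-12)
  expect_equal(sel$index, which.min(md))
})

test_that("identical instances give zero distances and the lowest index", {
  w <- small_bundle(n_nodes = 20, volume = 2, seed = 9)$weights
  sel <- select_representative(list(w, w, w, w, w))
  expect_equal(sel$index, 1)
  expect_equal(sel$mean_distance, rep(0, 5))
  expect_false(any(sel$outlier))
})

test_that("a heavily rewired instance is flagged as outlier", {
  b <- small_bundle(n_nodes = 30, volume = 5, seed = 7)
  inst <- c(jitter_replicates(b, n = 9, jitter_sd = 0.02, seed = 4),
            jitter_replicates(b, n = 1, jitter_sd = 0.02, rewire_frac = 0.6,
                              seed = 5))
  sel <- select_representative(inst)
  # verify the flag against a direct scaled-MAD computation
  md <- sel$mean_distance
  direct <- md > median(md) + 3 * mad(md)
  expect_identical(sel$outlier, direct)
  expect_true(sel$outlier[10])
  expect_false(any(sel$outlier[1:9]))
})

test_that("cohort outlier flags follow the MAD rule and are equivariant", {
  m <- 10
  npd <- matrix(0.02, m, m); diag(npd) <- 0
  npd[m, ] <- npd[, m] <- 0.2; npd[m, m] <- 0
  orders <- rep(c("a", "b"), each = 5)
  fl <- flag_cohort_outliers(npd, orders)
  expect_true(fl$flagged[m])
  expect_false(any(fl$flagged[1:(m - 1)]))
  # homogeneous cohort: no flags
  npd0 <- matrix(0.1, m, m); diag(npd0) <- 0
  expect_false(any(flag_cohort_outliers(npd0, orders)$flagged))
  # permuting items permutes flags identically
  perm <- sample(m)
  fl_p <- flag_cohort_outliers(npd[perm, perm], orders[perm])
  expect_identical(fl_p$flagged, fl$flagged[perm])
  # single-member order exempt from the z rule
  fl_s <- flag_cohort_outliers(npd, c(rep("a", 9), "solo"))
  expect_true(fl_s$z_exempt[10])
  expect_true(is.na(fl_s$z_within[10]))
})
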