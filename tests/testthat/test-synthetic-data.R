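test_that("volume table obeys the configured power laws and contract", {
  spec <- cohort_spec(n_animals = 10, n_nodes = 20, noise_sd = 0, seed = 11)
  vt <- generate_volume_table(spec)
  expect_equal(nrow(vt), 10)
  expect_true(all(vt$bv_cm3 >= spec$volume_range[1] &
                    vt$bv_cm3 <= spec$volume_range[2]))
  expect_true(all(vt$gm_mm3 > 0 & vt$wm_mm3 > 0))
  # noiseless: regressing log10 WM on log10 GM recovers the law exactly
  fit <- lm(log10(wm_mm3) ~ log10(gm_mm3), data = vt)
  expect_equal(unname(coef(fit)[2]), 1.16, tolerance = 1e-12)
  expect_equal(unname(coef(fit)[1]), -1.45, tolerance = 1e-10)
  fit2 <- lm(log10(gm_mm3) ~ log10(bv_mm3), data = vt)
  expect_equal(unname(coef(fit2)[2]), 0.98, tolerance = 1e-12)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-12)
})

test_that("volume table is deterministic under seed", {
  spec <- cohort_spec(n_animals = 8, n_nodes = 20, seed = 3)
  expect_identical(generate_volume_table(spec), generate_volume_table(spec))
})

test_that("spec validation rejects bad parameters", {
  expect_error(cohort_spec(volume_range = c(5, 1)), "volume_range")
  expect_error(cohort_spec(noise_sd = -0.1), "noise_sd")
  expect_error(cohort_spec(n_nodes = 7), "n_nodes")
  expect_error(cohort_spec(target_density = 0), "target_density")
  expect_error(cohort_spec(n_modules = 1), "n_modules")
})

test_that("generated connectomes satisfy the structural contract", {
  spec <- cohort_spec(n_animals = 2, n_nodes = 60, seed = 21)
  b <- generate_connectome(5, spec, seed = 21)
  w <- b$weights
  n <- nrow(w)
  expect_identical(w, t(w))
  expect_true(all(diag(w) == 0))
  expect_true(all(w >= 0))
  dens <- sum(w[upper.tri(w)] > 0) / (n * (n - 1) / 2)
  expect_lt(abs(dens - spec$target_density) / spec$target_density, 0.1)
  expect_equal(sum(b$hemisphere == "L"), n / 2)
  expect_equal(sum(b$hemisphere == "R"), n / 2)
  # fiber length = 1.2 x ED exactly on the support, zero elsewhere
  ed <- euclidean_distances(b)
  fl <- as.matrix(b$fiber_length)
  expect_equal(fl[w > 0], 1.2 * ed[w > 0], tolerance = 1e-12)
  expect_true(all(fl[w == 0] == 0))
  expect_length(b$planted_partition, n)
  # coordinates mirror across the midline
  half <- n / 2
  expect_equal(b$coordinates[1:half, 1], -b$coordinates[(half + 1):n, 1])
  expect_true(igraph::is_connected(
    igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")))
})

test_that("zero module boost gives equal within/between edge density", {
  spec <- cohort_spec(n_animals = 2, n_nodes = 60, within_module_boost = 0,
                      spatial_decay_base = 50, # ~distance-flat, isolates boost
                      spatial_decay_volume_coupling = 0, seed = 2)
  ratios <- sapply(1:20, function(s) {
    b <- generate_connectome(10, spec, seed = s)
    w <- b$weights > 0
    same <- outer(b$planted_partition, b$planted_partition, "==")
    ut <- upper.tri(w)
    mean(w[ut & same]) / mean(w[ut & !same])
  })
  expect_gt(mean(ratios), 0.8)
  expect_lt(mean(ratios), 1.2)
})

test_that("volume-coupled decay plants shrinking normalized edge lengths", {
  spec <- cohort_spec(n_animals = 20, n_nodes = 60,
                      spatial_decay_volume_coupling = 0.12, seed = 5)
  vols <- 10^seq(log10(spec$volume_range[1]), log10(spec$volume_range[2]),
                 length.out = 20)
  mean_ed <- sapply(seq_along(vols), function(i) {
    b <- generate_connectome(vols[i], spec, seed = i)
    ed <- euclidean_distances(b) / vols[i]^(1 / 3) # normalized units
    mean(ed[b$weights > 0])
  })
  expect_lt(cor(vols, mean_ed, method = "spearman"), 0)
})

test_that("larger module boost raises planted-partition modularity", {
  qs <- sapply(c(0, 2, 6), function(boost) {
    spec <- cohort_spec(n_animals = 2, n_nodes = 60,
                        within_module_boost = boost, seed = 9)
    b <- generate_connectome(10, spec, seed = 9)
    modularity_score(b$weights, b$planted_partition, gamma = 1)
  })
  expect_true(all(diff(qs) > 0))
})

test_that("cohorts are reproducible and carry metadata", {
  spec <- cohort_spec(n_animals = 5, n_nodes = 40, seed = 13)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_equal(length(c1$bundles), 5)
  expect_identical(c1$volumes, c2$volumes)
  expect_identical(lapply(c1$bundles, `[[`, "weights"),
                   lapply(c2$bundles, `[[`, "weights"))
  b <- c1$bundles[[3]]
  expect_equal(b$metadata$id, c1$volumes$animal_id[3])
  expect_equal(b$metadata$bv_cm3, c1$volumes$bv_cm3[3])
  expect_equal(nrow(b$weights), 40)
})
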