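#' Modularity of a partition at resolution gamma
#'
#' Evaluates Q(gamma) = (1/2m) * sum_ij \[W_ij - gamma * k_i k_j / 2m\]
#' delta(sigma_i, sigma_j) under the configuration null, the standard
#' objective for sparse positively weighted networks. Q is reported
#' normalized by the total weight 2m, which leaves the argmax over partitions
#' unchanged at fixed gamma and makes values comparable across networks.
#' Diagonal terms enter through the null (self-pair null mass k_i^2/2m), per
#' the configuration-model convention.
#'
#' @param weights symmetric non-negative weight matrix.
#' @param partition integer (or factor) module labels, one per node.
#' @param gamma resolution parameter; larger values favor smaller modules.
#' @return Scalar Q.
#' @export
modularity_score <- function(weights, partition, gamma = 1) {
  .check_weights(weights)
  if (gamma <= 0) abort("`gamma` must be positive")
  sigma <- as.integer(as.factor(partition))
  if (length(sigma) != nrow(weights)) abort("partition length mismatch")
  k <- rowSums(weights)
  two_m <- sum(k)
  if (two_m == 0) abort("empty graph: total weight is zero")
  same <- outer(sigma, sigma, "==")
  sum((weights - gamma * outer(k, k) / two_m) * same) / two_m
}

.as_igraph <- function(weights) {
  igraph::graph_from_adjacency_matrix(weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Louvain modularity optimization at a single resolution
#'
#' One greedy Louvain run with seeded random initialization; optionally the
#' best of `n_restarts` independent runs (by Q). Returns a `partition`
#' object recording the labeling, the resolution, and Q.
#'
#' @param weights symmetric non-negative weight matrix.
#' @param gamma resolution parameter.
#' @param seed integer seed.
#' @param n_restarts keep the max-Q partition over this many runs.
#' @return A `partition`: list with `sigma` (integer labels from 1), `gamma`,
#'   `q`, `n_modules`.
#' @export
optimize_partition <- function(weights, gamma = 1, seed = 1L, n_restarts = 1L) {
  .check_weights(weights)
  g <- .as_igraph(weights)
  n <- nrow(weights)
  # trivial baselines: the returned partition never scores below either
  candidates <- list(seq_len(n), rep(1L, n))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(.derive_seed(seed, r - 1L))
    cl <- igraph::cluster_louvain(g, resolution = gamma)
    candidates[[length(candidates) + 1L]] <- as.integer(igraph::membership(cl))
  }
  for (sigma in candidates) {
    q <- modularity_score(weights, sigma, gamma)
    if (is.null(best) || q > best$q) {
      best <- list(sigma = sigma, gamma = gamma, q = q,
                   n_modules = length(unique(sigma)))
    }
  }
  structure(best, class = "partition")
}

#' Two-step multiresolution partition ensemble
#'
#' Step 1 sweeps `n_gamma` logarithmically spaced resolutions over
#' `coarse_range` (one Louvain run each) and brackets the informative range:
#' `gamma_L` is the smallest resolution yielding at least 2 modules and
#' `gamma_H` the largest yielding at most N/2. Step 2 re-sweeps `n_gamma`
#' log-spaced resolutions inside `[gamma_L, gamma_H]`; partitions whose
#' module count falls outside \[2, N/2\] are dropped, so the retained
#' ensemble spans coarse-to-fine scales while excluding trivial and
#' near-singleton partitions.
#'
#' @param weights symmetric non-negative weight matrix.
#' @param n_gamma resolutions per step (500 for full-scale runs; smaller
#'   grids give faster, slightly coarser consensus).
#' @param coarse_range length-2 positive range for the step-1 sweep.
#' @param seed integer seed.
#' @param gamma_range optional length-2 range \[gamma_L, gamma_H\]; when
#'   supplied, step 1 is skipped and the sweep runs directly over this range
#'   (used for cohort-wide joint bracketing, where the same range must serve
#'   every animal).
#' @return A `partition_ensemble`: list of retained `partition`s plus
#'   `gamma_l`, `gamma_h`, and the step-2 grid.
#' @export
mrcc_ensemble <- function(weights, n_gamma = 500L,
                          coarse_range = c(0.01, 10), seed = 1L,
                          gamma_range = NULL) {
  .check_weights(weights)
  n <- nrow(weights)
  if (is.null(gamma_range)) {
    br <- mrcc_bracket(weights, n_gamma, coarse_range, seed)
    gamma_l <- br$gamma_l
    gamma_h <- br$gamma_h
  } else {
    if (length(gamma_range) != 2 || any(gamma_range <= 0) ||
        diff(gamma_range) < 0) {
      abort("`gamma_range` must be positive and non-decreasing")
    }
    gamma_l <- gamma_range[1]
    gamma_h <- gamma_range[2]
  }
  g <- .as_igraph(weights)
  run_grid <- function(gammas, seed0) {
    purrr::map(seq_along(gammas), function(i) {
      set.seed(.derive_seed(seed0, i))
      cl <- igraph::cluster_louvain(g, resolution = gammas[i])
      sigma <- as.integer(igraph::membership(cl))
      structure(list(sigma = sigma, gamma = gammas[i],
                     q = modularity_score(weights, sigma, gammas[i]),
                     n_modules = length(unique(sigma))),
                class = "partition")
    })
  }
  grid2 <- if (gamma_h > gamma_l) {
    exp(seq(log(gamma_l), log(gamma_h), length.out = n_gamma))
  } else rep(gamma_l, n_gamma)
  step2 <- run_grid(grid2, .derive_seed(seed, 2L))
  keep <- vapply(step2, function(p) {
    p$n_modules >= 2 && p$n_modules <= n %/% 2
  }, logical(1))
  if (!any(keep)) abort("no retained partition in [2, N/2]; check gamma range")
  structure(list(partitions = step2[keep], gamma_l = gamma_l,
                 gamma_h = gamma_h, gamma_grid = grid2,
                 n_dropped = sum(!keep)),
            class = "partition_ensemble")
}

#' Bracket the informative resolution range of one network
#'
#' Step 1 of the multiresolution sweep: `n_gamma` log-spaced resolutions over
#' `coarse_range`, one Louvain run each; returns the smallest resolution
#' yielding at least 2 modules (`gamma_l`) and the largest yielding at most
#' N/2 (`gamma_h`). Cohort analyses intersect these brackets across animals
#' so a single range serves every species.
#'
#' @inheritParams mrcc_ensemble
#' @return List with `gamma_l`, `gamma_h`.
#' @export
mrcc_bracket <- function(weights, n_gamma = 500L,
                         coarse_range = c(0.01, 10), seed = 1L) {
  .check_weights(weights)
  if (length(coarse_range) != 2 || any(coarse_range <= 0) ||
      diff(coarse_range) <= 0) {
    abort("`coarse_range` must be positive and increasing")
  }
  n <- nrow(weights)
  g <- .as_igraph(weights)
  grid1 <- exp(seq(log(coarse_range[1]), log(coarse_range[2]),
                   length.out = n_gamma))
  n_mod <- vapply(seq_along(grid1), function(i) {
    set.seed(.derive_seed(.derive_seed(seed, 1L), i))
    length(unique(igraph::membership(
      igraph::cluster_louvain(g, resolution = grid1[i]))))
  }, integer(1))
  ok_low <- which(n_mod >= 2)
  ok_high <- which(n_mod <= n %/% 2)
  if (length(ok_low) == 0) {
    abort("no resolution yields >= 2 modules; widen `coarse_range` upward")
  }
  gamma_l <- grid1[min(ok_low)]
  gamma_h <- if (length(ok_high)) grid1[max(ok_high)] else grid1[n_gamma]
  if (gamma_h < gamma_l) gamma_h <- gamma_l
  list(gamma_l = gamma_l, gamma_h = gamma_h)
}

#' @export
print.partition_ensemble <- function(x, ...) {
  cat(sprintf(
    "<partition_ensemble> %d partitions over gamma [%.4g, %.4g] (%d dropped)\n",
    length(x$partitions), x$gamma_l, x$gamma_h, x$n_dropped))
  invisible(x)
}

#' Co-classification (agreement) matrix of a partition ensemble
#'
#' `CC[i, j]` is the fraction of ensemble partitions assigning nodes i and j
#' to the same module — the probability, across the resolution spectrum, that
#' the pair co-classifies.
#'
#' @param ensemble a `partition_ensemble` (or plain list of `partition`s).
#' @return N x N symmetric matrix with unit diagonal, entries in \[0, 1\].
#' @export
coclassification_matrix <- function(ensemble) {
  parts <- if (inherits(ensemble, "partition_ensemble")) ensemble$partitions
           else ensemble
  if (length(parts) == 0) abort("empty partition ensemble")
  n <- length(parts[[1]]$sigma)
  cc <- matrix(0, n, n)
  for (p in parts) {
    cc <- cc + outer(p$sigma, p$sigma, "==")
  }
  cc / length(parts)
}

#' Consensus partition from a co-classification matrix
#'
#' Clusters the agreement matrix itself: Louvain at resolution 1 under the
#' configuration null, best of `n_restarts` seeded runs by Q.
#'
#' @param cc co-classification matrix (symmetric, unit diagonal).
#' @param seed integer seed.
#' @param n_restarts number of restarts (default 100).
#' @return A `partition`.
#' @export
consensus_from_cc <- function(cc, seed = 1L, n_restarts = 100L) {
  if (!isTRUE(all.equal(cc, t(cc), tolerance = 1e-10))) {
    abort("`cc` must be symmetric")
  }
  w <- cc
  diag(w) <- 0
  optimize_partition(w, gamma = 1, seed = seed, n_restarts = n_restarts)
}

#' Module-level features of a consensus partition
#'
#' Two global descriptors of modular structure:
#' * intramodule density (IMD): mean over modules of the realized
#'   within-module edge density (singleton modules are excluded — their
#'   density is undefined);
#' * long-distance fraction: the number of the top-5%-longest existing edges
#'   (by Euclidean distance) whose endpoints lie in different modules,
#'   normalized by the total module count.
#'
#' @param weights symmetric non-negative weight matrix.
#' @param ed_matrix Euclidean distance matrix between node centroids.
#' @param consensus a `partition` (or plain label vector).
#' @param longdist_quantile fraction of longest edges considered
#'   "long-distance" (default 0.05).
#' @return Named list `imd`, `longdist_fraction`, `n_modules`.
#' @export
partition_features <- function(weights, ed_matrix, consensus,
                               longdist_quantile = 0.05) {
  .check_weights(weights)
  sigma <- if (inherits(consensus, "partition")) consensus$sigma
           else as.integer(as.factor(consensus))
  n <- nrow(weights)
  if (length(sigma) != n) abort("partition length mismatch")
  sizes <- table(sigma)
  non_single <- as.integer(names(sizes)[sizes >= 2])
  if (length(non_single) == 0) {
    abort("all modules are singletons: intramodule density undefined")
  }
  dens <- vapply(non_single, function(m) {
    idx <- which(sigma == m)
    nm <- length(idx)
    sub <- weights[idx, idx]
    sum(sub[.ut(nm)] > 0) / (nm * (nm - 1) / 2)
  }, numeric(1))
  imd <- mean(dens)

  edges <- .edge_list(weights)
  edges$ed <- ed_matrix[cbind(edges$i, edges$j)]
  n_top <- ceiling(longdist_quantile * nrow(edges))
  # longest edges first; ties by ascending (i, j) for determinism
  ord <- order(-edges$ed, edges$i, edges$j)
  top <- edges[ord[seq_len(n_top)], ]
  n_between <- sum(sigma[top$i] != sigma[top$j])
  list(imd = imd,
       longdist_fraction = n_between / length(sizes),
       n_modules = length(sizes))
}

#' Interhemispheric co-classification index
#'
#' Mean agreement over inter-hemisphere node pairs divided by the mean
#' agreement over intra-hemisphere pairs (both hemispheres pooled). 0 when
#' modules align perfectly with the hemispheres, 1 when agreement is
#' hemisphere-blind.
#'
#' @param cc co-classification matrix.
#' @param hemisphere character vector of `"L"`/`"R"` labels.
#' @return Scalar index.
#' @export
interhemispheric_cc <- function(cc, hemisphere) {
  n <- nrow(cc)
  if (length(hemisphere) != n) abort("hemisphere labels length mismatch")
  if (!all(c("L", "R") %in% hemisphere)) abort("both hemispheres required")
  ut <- .ut(n)
  inter <- outer(hemisphere, hemisphere, "!=")
  num <- mean(cc[ut & inter])
  den <- mean(cc[ut & !inter])
  if (den == 0) abort("degenerate CC: zero intra-hemisphere agreement")
  num / den
}
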