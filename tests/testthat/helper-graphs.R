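# fixture graphs ------------------------------------------------------------

sym_from_edges <- function(n, edges) {
  # edges: data.frame/matrix with columns i, j, w
  w <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    w[edges[r, 1], edges[r, 2]] <- w[edges[r, 2], edges[r, 1]] <- edges[r, 3]
  }
  w
}

k2 <- function(w = 1) sym_from_edges(2, cbind(1, 2, w))

path3 <- function() sym_from_edges(3, rbind(c(1, 2, 1), c(2, 3, 1)))

triangle <- function() {
  sym_from_edges(3, rbind(c(1, 2, 1), c(1, 3, 1), c(2, 3, 1)))
}

two_cliques <- function(k = 4) {
  n <- 2 * k
  w <- matrix(0, n, n)
  w[1:k, 1:k] <- 1
  w[(k + 1):n, (k + 1):n] <- 1
  diag(w) <- 0
  w[k, k + 1] <- w[k + 1, k] <- 1 # single bridge
  w
}

two_dyads <- function() {
  sym_from_edges(4, rbind(c(1, 2, 1), c(3, 4, 1)))
}

# connected Erdos-Renyi-style weighted graph
random_weighted_graph <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    w <- matrix(0, n, n)
    ut <- upper.tri(w)
    on <- runif(sum(ut)) < p
    vals <- ifelse(on, runif(sum(ut), 0.1, 2), 0)
    w[ut] <- vals
    w <- w + t(w)
    g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
    if (igraph::is_connected(g)) return(w)
  }
}

# k-block stochastic block model with unit weights
sbm_graph <- function(n = 100, k = 4, p_in = 0.4, p_out = 0.05, seed = 1) {
  set.seed(seed)
  blocks <- rep(seq_len(k), length.out = n)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  same <- outer(blocks, blocks, "==")
  p <- ifelse(same, p_in, p_out)
  w[ut] <- as.numeric(runif(sum(ut)) < p[ut])
  w <- w + t(w)
  list(weights = w, blocks = blocks)
}

small_bundle <- function(n_nodes = 40, volume = 10, seed = 5, ...) {
  spec <- cohort_spec(n_animals = 2, n_nodes = n_nodes, seed = seed, ...)
  generate_connectome(volume, spec, seed = seed)
}

# independent oracles --------------------------------------------------------

# textbook O(n^2) Dijkstra, coded independently of the package
dijkstra_oracle <- function(weights, source) {
  n <- nrow(weights)
  len <- ifelse(weights > 0, 1 / weights, Inf)
  dist <- rep(Inf, n)
  dist[source] <- 0
  visited <- rep(FALSE, n)
  for (step in seq_len(n)) {
    u <- which(!visited & dist == min(dist[!visited]))[1]
    if (is.na(u) || is.infinite(dist[u])) break
    visited[u] <- TRUE
    for (v in which(len[u, ] < Inf)) {
      if (dist[u] + len[u, v] < dist[v]) dist[v] <- dist[u] + len[u, v]
    }
  }
  dist
}

# exhaustive simple-path enumeration: shortest path(s) and their
# transition-probability products, for tiny graphs only
enumerate_si_oracle <- function(weights, i, j) {
  n <- nrow(weights)
  len <- ifelse(weights > 0, 1 / weights, Inf)
  s <- rowSums(weights)
  best_len <- Inf
  best_paths <- list()
  rec <- function(path, total) {
    cur <- path[length(path)]
    if (total > best_len + 1e-12) return()
    if (cur == j) {
      if (total < best_len - 1e-12) {
        best_len <<- total
        best_paths <<- list(path)
      } else {
        best_paths <<- c(best_paths, list(path))
      }
      return()
    }
    for (v in which(len[cur, ] < Inf)) {
      if (!(v %in% path)) rec(c(path, v), total + len[cur, v])
    }
  }
  rec(i, 0)
  if (length(best_paths) == 0) return(NA_real_)
  # lexicographically smallest shortest path, as the implementation documents
  keys <- vapply(best_paths, function(p) paste(sprintf("%04d", p), collapse = ""),
                 character(1))
  path <- best_paths[[order(keys)[1]]]
  p <- 1
  for (step in seq_len(length(path) - 1)) {
    u <- path[step]; v <- path[step + 1]
    p <- p * weights[u, v] / s[u]
  }
  -log2(p)
}

# 30-term power-series matrix exponential
expm_series_oracle <- function(m, terms = 30) {
  out <- diag(nrow(m))
  term <- diag(nrow(m))
  for (k in seq_len(terms)) {
    term <- term %*% m / k
    out <- out + term
  }
  out
}

# rank-then-Pearson Spearman oracle
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# base-2 Jensen-Shannon divergence of two distributions
jsd_oracle <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

# all set partitions of 1..n (for brute-force modularity maximization)
all_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in all_partitions(n - 1)) {
    for (b in seq_along(p)) {
      q <- p
      q[[b]] <- c(q[[b]], n)
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(p, list(n))
  }
  out
}

blocks_to_labels <- function(p, n) {
  lab <- integer(n)
  for (b in seq_along(p)) lab[p[[b]]] <- b
  lab
}

md5sum_dir <- function(dir) {
  files <- sort(list.files(dir, full.names = TRUE))
  setNames(tools::md5sum(files), basename(files))
}
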