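#' Maximum-weight spanning-tree backbone
#'
#' The N-1 strongest edges forming a connected skeleton, found by Kruskal's
#' algorithm on descending weight. Ties between equal-weight edges are broken
#' by ascending (i, j) node index, so the backbone is deterministic.
#'
#' @param weights symmetric non-negative weight matrix of a connected graph.
#' @return Tibble of backbone edges (`i`, `j`, `w`), `i < j`.
#' @export
mst_backbone <- function(weights) {
  .check_weights(weights)
  n <- nrow(weights)
  g <- .as_igraph(weights)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    abort(sprintf("graph is disconnected (%d components of sizes %s)",
                  comp$no, paste(comp$csize, collapse = ", ")))
  }
  edges <- .edge_list(weights)
  edges <- edges[order(-edges$w, edges$i, edges$j), ]
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- logical(nrow(edges))
  taken <- 0L
  for (e in seq_len(nrow(edges))) {
    ri <- find(edges$i[e]); rj <- find(edges$j[e])
    if (ri != rj) {
      parent[ri] <- rj
      keep[e] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  out <- edges[keep, ]
  out[order(out$i, out$j), ]
}

#' Threshold a network to a fixed edge density
#'
#' Keeps the maximum-weight spanning-tree backbone (guaranteeing
#' connectivity) and adds the remaining edges in order of descending weight
#' until `ceil(d * N(N-1)/2)` edges survive. Surviving weights are unchanged.
#' Ties in weight are broken by ascending (i, j).
#'
#' @param weights symmetric non-negative weight matrix (connected).
#' @param d target edge density in (0, 1\]; must be at least the backbone
#'   density (N-1 edges).
#' @return Thresholded weight matrix (same dimensions, symmetric).
#' @export
threshold_to_density <- function(weights, d) {
  .check_weights(weights)
  n <- nrow(weights)
  n_pairs <- n * (n - 1) / 2
  if (d <= 0 || d > 1) abort("`d` must be in (0, 1]")
  target <- ceiling(d * n_pairs)
  if (target < n - 1) {
    abort(sprintf("density %.4g below backbone density; minimum achievable d = %.4g",
                  d, (n - 1) / n_pairs))
  }
  backbone <- mst_backbone(weights)
  edges <- .edge_list(weights)
  if (target >= nrow(edges)) return(weights) # support already at/below target
  in_backbone <- paste(edges$i, edges$j) %in% paste(backbone$i, backbone$j)
  rest <- edges[!in_backbone, ]
  rest <- rest[order(-rest$w, rest$i, rest$j), ]
  n_extra <- target - nrow(backbone)
  chosen <- bind_rows(backbone, rest[seq_len(n_extra), ])
  out <- matrix(0, n, n)
  out[cbind(chosen$i, chosen$j)] <- chosen$w
  out + t(out)
}
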