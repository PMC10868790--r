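#' Mantel-style permutations of a co-classification matrix
#'
#' Each draw applies one random node permutation jointly to the rows and
#' columns of the matrix, preserving its value multiset, symmetry and unit
#' diagonal while destroying the node correspondence — the null used to test
#' couplings between CC and other node-pair matrices.
#'
#' @param cc symmetric node-pair matrix (co-classification or similar).
#' @param n_perm number of permuted draws (default 1000).
#' @param seed integer seed.
#' @return List of `n_perm` permuted matrices.
#' @export
permute_cc_mantel <- function(cc, n_perm = 1000L, seed = 1L) {
  if (!is.matrix(cc) || nrow(cc) != ncol(cc)) abort("`cc` must be square")
  if (n_perm < 1) abort("`n_perm` must be >= 1")
  n <- nrow(cc)
  purrr::map(seq_len(n_perm), function(b) {
    set.seed(.derive_seed(seed, b))
    p <- sample.int(n)
    cc[p, p]
  })
}

#' Permute module allegiance of a partition
#'
#' Shuffles the node-to-module assignment while preserving the number and
#' size of modules exactly (the label vector is permuted across nodes).
#'
#' @param partition a `partition` object or plain label vector.
#' @param seed integer seed.
#' @return Same type as the input, with permuted labels.
#' @export
permute_partition_labels <- function(partition, seed = 1L) {
  sigma <- if (inherits(partition, "partition")) partition$sigma else partition
  set.seed(.derive_seed(seed, 0L))
  perm <- sigma[sample.int(length(sigma))]
  if (inherits(partition, "partition")) {
    partition$sigma <- perm
    partition
  } else {
    perm
  }
}

#' Geometry- and degree-preserving rewiring by distance bins
#'
#' Partitions the edges into `n_bins` equal-count bins of Euclidean distance
#' and applies degree-preserving double-edge swaps only between edge pairs in
#' the same bin. The degree sequence is preserved exactly, per-bin edge
#' counts are preserved by construction, and weights travel with their edge,
#' so weight-length coupling is broken only at bin resolution — a surrogate
#' retaining the original geometry and degrees while shuffling topology.
#'
#' @param bundle a [connectome_bundle()] (weights + coordinates).
#' @param n_bins equal-count distance bins (default 10).
#' @param n_swaps_per_edge attempted swaps per edge within each bin
#'   (default 10).
#' @param seed integer seed.
#' @return Rewired weight matrix.
#' @export
distance_binned_rewire <- function(bundle, n_bins = 10L,
                                   n_swaps_per_edge = 10L, seed = 1L) {
  stopifnot(inherits(bundle, "connectome_bundle"))
  w <- bundle$weights
  n <- nrow(w)
  ed <- euclidean_distances(bundle)
  edges <- .edge_list(w)
  edges$ed <- ed[cbind(edges$i, edges$j)]
  # equal-count bins by distance rank
  edges$bin <- ceiling(rank(edges$ed, ties.method = "first") *
                         n_bins / nrow(edges))
  set.seed(.derive_seed(seed, 0L))
  adj <- w > 0
  ei <- edges$i; ej <- edges$j; ew <- edges$w; ebin <- edges$bin
  for (b in seq_len(n_bins)) {
    members <- which(ebin == b)
    if (length(members) < 2) {
      warn(sprintf("distance bin %d has < 2 edges; skipped", b))
      next
    }
    n_attempts <- n_swaps_per_edge * length(members)
    for (att in seq_len(n_attempts)) {
      pick <- sample(members, 2)
      e1 <- pick[1]; e2 <- pick[2]
      a <- ei[e1]; bb <- ej[e1]; cc_ <- ei[e2]; dd <- ej[e2]
      # propose (a,b)+(c,d) -> (a,d)+(c,b); reject self- and multi-edges
      if (a == dd || cc_ == bb) next
      if (adj[a, dd] || adj[cc_, bb]) next
      adj[a, bb] <- adj[bb, a] <- FALSE
      adj[cc_, dd] <- adj[dd, cc_] <- FALSE
      adj[a, dd] <- adj[dd, a] <- TRUE
      adj[cc_, bb] <- adj[bb, cc_] <- TRUE
      ej[e1] <- dd
      ej[e2] <- bb
      # keep i < j orientation
      if (ei[e1] > ej[e1]) { tmp <- ei[e1]; ei[e1] <- ej[e1]; ej[e1] <- tmp }
      if (ei[e2] > ej[e2]) { tmp <- ei[e2]; ei[e2] <- ej[e2]; ej[e2] <- tmp }
    }
  }
  out <- matrix(0, n, n)
  out[cbind(ei, ej)] <- ew
  out[cbind(ej, ei)] <- ew
  out
}
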