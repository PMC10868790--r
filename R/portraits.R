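#' Quantile bin edges for portrait construction
#'
#' Pools the finite positive shortest-path distances of a set of networks and
#' returns the edges of `n_bins` equal-probability (quantile) bins. Holding
#' the same edges across networks keeps their portraits comparable.
#'
#' @param weight_list list of weight matrices (or a single matrix).
#' @param n_bins number of quantile bins (default 25).
#' @return Increasing numeric vector of `n_bins + 1` edges.
#' @export
portrait_bin_edges <- function(weight_list, n_bins = 25L) {
  if (is.matrix(weight_list)) weight_list <- list(weight_list)
  pooled <- unlist(lapply(weight_list, function(w) {
    d <- .sp_lengths(w)
    v <- d[.ut(nrow(d))]
    v[is.finite(v) & v > 0]
  }))
  if (length(pooled) == 0) abort("no finite positive distances to bin")
  edges <- unname(quantile(pooled, probs = seq(0, 1, length.out = n_bins + 1)))
  edges[1] <- 0                       # left-open bins catch every distance
  edges[length(edges)] <- edges[length(edges)] * (1 + 1e-9)
  # heavy ties can collapse quantiles; drop duplicates to keep bins valid
  unique(edges)
}

#' Network portrait
#'
#' The portrait `B` is a histogram matrix whose entry `B[l, k+1]` counts the
#' nodes that have exactly `k` other nodes at (binned) shortest-path distance
#' `l`. Distances use edge lengths 1/weight and are discretized into quantile
#' bins; unreachable pairs land in a dedicated overflow bin so disconnected
#' graphs remain comparable.
#'
#' @param weights symmetric non-negative weight matrix (or a
#'   [connectome_bundle()]).
#' @param bin_edges increasing numeric bin edges; when `NULL`, 25-quantile
#'   edges are computed from this network alone. Supply shared edges
#'   (from [portrait_bin_edges()]) when comparing networks.
#' @param n_bins bins used when `bin_edges` is `NULL`.
#' @return A `portrait`: list with matrix `b` (rows: bins + overflow,
#'   columns: k = 0..N-1), `bin_edges`, `n`.
#' @export
compute_portrait <- function(weights, bin_edges = NULL, n_bins = 25L) {
  if (inherits(weights, "connectome_bundle")) weights <- weights$weights
  .check_weights(weights)
  n <- nrow(weights)
  if (n < 2) abort("portrait requires at least 2 nodes")
  if (is.null(bin_edges)) bin_edges <- portrait_bin_edges(weights, n_bins)
  if (any(diff(bin_edges) <= 0)) abort("`bin_edges` must be strictly increasing")
  d <- .sp_lengths(weights)
  n_bins_eff <- length(bin_edges) - 1
  n_rows <- n_bins_eff + 1 # + overflow row for unreachable pairs
  b <- matrix(0L, n_rows, n)
  for (i in seq_len(n)) {
    di <- d[i, -i]
    bin <- findInterval(di, bin_edges, left.open = TRUE, all.inside = FALSE)
    bin[di > bin_edges[length(bin_edges)] | is.infinite(di)] <- n_rows
    bin[bin < 1] <- 1
    bin[bin > n_rows] <- n_rows
    counts <- tabulate(bin, nbins = n_rows)
    for (l in seq_len(n_rows)) {
      k <- counts[l]
      b[l, k + 1] <- b[l, k + 1] + 1L
    }
  }
  structure(list(b = b, bin_edges = bin_edges, n = n), class = "portrait")
}

# joint (l, k) distribution of a portrait: row l weighted by the fraction of
# node pairs at binned distance l, within-row mass proportional to k * B[l,k]
.portrait_distribution <- function(p) {
  b <- p$b
  k <- matrix(rep(0:(ncol(b) - 1), each = nrow(b)), nrow(b))
  mass <- k * b
  tot <- sum(mass)
  if (tot == 0) abort("degenerate portrait: no node pairs")
  mass / tot
}

#' Network portrait divergence (NPD)
#'
#' Base-2 Jensen-Shannon divergence between the joint (distance-bin,
#' neighbor-count) distributions of two portraits built on shared bin edges.
#' Symmetric, zero for identical portraits, bounded in \[0, 1\].
#'
#' @param a,b `portrait` objects with identical `bin_edges`.
#' @return Scalar divergence in \[0, 1\].
#' @export
portrait_divergence <- function(a, b) {
  stopifnot(inherits(a, "portrait"), inherits(b, "portrait"))
  if (length(a$bin_edges) != length(b$bin_edges) ||
      any(abs(a$bin_edges - b$bin_edges) > 1e-12)) {
    abort("portraits must share identical bin_edges")
  }
  pa <- .portrait_distribution(a)
  pb <- .portrait_distribution(b)
  kmax <- max(ncol(pa), ncol(pb))
  pad <- function(m) cbind(m, matrix(0, nrow(m), kmax - ncol(m)))
  pa <- pad(pa); pb <- pad(pb)
  mix <- (pa + pb) / 2
  kl <- function(p, q) {
    nz <- p > 0
    sum(p[nz] * log2(p[nz] / q[nz]))
  }
  0.5 * kl(pa, mix) + 0.5 * kl(pb, mix)
}

#' Pairwise NPD matrix over a set of networks
#'
#' Portraits are built on shared bin edges pooled from the whole set, so
#' divergences are comparable.
#'
#' @param weight_list list of weight matrices.
#' @param n_bins quantile bins (default 25).
#' @return Symmetric matrix of divergences with zero diagonal.
#' @export
npd_matrix <- function(weight_list, n_bins = 25L) {
  m <- length(weight_list)
  if (m < 2) abort("need at least 2 networks")
  edges <- portrait_bin_edges(weight_list, n_bins)
  ports <- lapply(weight_list, compute_portrait, bin_edges = edges)
  d <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      d[i, j] <- d[j, i] <- portrait_divergence(ports[[i]], ports[[j]])
    }
  }
  d
}

# robust outlier rule shared by centroid selection and cohort screening
.mad_flags <- function(x) {
  x > median(x) + 3 * mad(x) # mad() applies the 1.4826 consistency constant
}

#' Select the representative (centroid) network among instances
#'
#' Computes pairwise NPD with shared bins, removes instances whose mean
#' distance to the others exceeds the median by more than 3 scaled median
#' absolute deviations, and returns the surviving instance with minimal mean
#' distance (lowest index on ties).
#'
#' @param instances list (>= 2) of weight matrices of equal size.
#' @param n_bins quantile bins for the shared portrait discretization.
#' @return List: `index` of the representative, `mean_distance` per instance,
#'   `outlier` flags, `npd` matrix.
#' @export
select_representative <- function(instances, n_bins = 25L) {
  if (length(instances) < 2) abort("need at least 2 instances")
  npd <- npd_matrix(instances, n_bins)
  mean_d <- rowSums(npd) / (ncol(npd) - 1)
  out <- .mad_flags(mean_d)
  if (all(out)) abort("degenerate ensemble: every instance flagged as outlier")
  keep <- which(!out)
  idx <- keep[which.min(mean_d[keep])]
  list(index = idx, mean_distance = mean_d, outlier = out, npd = npd)
}

#' Flag outlier animals in a cohort NPD matrix
#'
#' Two rules mirror the dataset-screening procedure: (i) animals whose
#' cohort-mean divergence exceeds the median by more than 3 scaled MADs;
#' (ii) animals atypical for their own taxonomic order — within-order
#' strength z-score (computed on the divergence matrix restricted to the
#' order) greater than 3. Orders with a single member are exempt from rule
#' (ii) (the z-score is undefined) and noted in the output.
#'
#' @param npd_matrix symmetric divergence matrix over animals.
#' @param order_labels taxonomic order per animal.
#' @return Tibble with per-animal `mean_distance`, `mad_flag`, `z_within`,
#'   `z_flag`, `flagged`, `z_exempt`.
#' @export
flag_cohort_outliers <- function(npd_matrix, order_labels) {
  m <- nrow(npd_matrix)
  if (ncol(npd_matrix) != m) abort("`npd_matrix` must be square")
  if (length(order_labels) != m) abort("`order_labels` length mismatch")
  mean_d <- rowSums(npd_matrix) / (m - 1)
  mad_flag <- .mad_flags(mean_d)
  z_within <- rep(NA_real_, m)
  z_exempt <- rep(FALSE, m)
  for (ord in unique(order_labels)) {
    idx <- which(order_labels == ord)
    if (length(idx) < 2) {
      z_exempt[idx] <- TRUE
      next
    }
    strength <- rowSums(npd_matrix[idx, idx, drop = FALSE])
    if (sd(strength) == 0) {
      z_within[idx] <- 0
    } else {
      z_within[idx] <- (strength - mean(strength)) / sd(strength)
    }
  }
  z_flag <- !is.na(z_within) & z_within > 3
  tibble(mean_distance = mean_d, mad_flag = mad_flag,
         z_within = z_within, z_flag = z_flag,
         flagged = mad_flag | z_flag, z_exempt = z_exempt)
}
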