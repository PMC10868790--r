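# weighted shortest-path length matrix with edge lengths = 1/weight
.sp_lengths <- function(weights) {
  g <- .as_igraph(weights)
  len <- 1 / igraph::E(g)$weight
  igraph::distances(g, weights = len, algorithm = "dijkstra")
}

#' Shortest-path efficiency
#'
#' Edge weights are converted to lengths L = 1/W; Pi\[i, j\] is the minimal
#' total length over paths between i and j, and SPE = 1/Pi elementwise. High
#' values mean the pair is joined by a strong, short route. Unreachable pairs
#' get SPE = 0; the diagonal is 0 by convention (excluded from analyses).
#'
#' @param weights symmetric non-negative weight matrix.
#' @return N x N symmetric SPE matrix.
#' @export
shortest_path_efficiency <- function(weights) {
  .check_weights(weights)
  pi_mat <- .sp_lengths(weights)
  spe <- 1 / pi_mat
  spe[is.infinite(pi_mat)] <- 0 # unreachable
  diag(spe) <- 0
  spe
}

#' Negative search information
#'
#' Search information SI_ij is the number of bits a random walker needs to
#' follow the shortest path from i to j: SI_ij = -log2 P(pi_{i->j}) with
#' P the product of transition probabilities p_uv = W_uv / s_u along the
#' path. The symmetric, "bigger is more efficient" form reported here is
#' NSI_ij = -(SI_ij + SI_ji) / 2. When several shortest paths tie exactly,
#' the lexicographically smallest node sequence is followed, so results are
#' deterministic. Pairs with no path are `NA` (masked invalid).
#'
#' @param weights symmetric non-negative weight matrix.
#' @param tol relative tolerance for detecting ties on path length.
#' @return N x N symmetric NSI matrix (non-positive; `NA` where undefined).
#' @export
negative_search_information <- function(weights, tol = 1e-12) {
  .check_weights(weights)
  n <- nrow(weights)
  pi_mat <- .sp_lengths(weights)
  len <- ifelse(weights > 0, 1 / weights, Inf)
  s <- rowSums(weights)
  logp <- log2(ifelse(weights > 0, weights / s, 0)) # log2 p_uv, -Inf off-support
  si <- matrix(NA_real_, n, n)
  scale_tol <- function(x) tol * pmax(1, abs(x))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { si[i, j] <- 0; next }
      if (is.infinite(pi_mat[i, j])) next
      cur <- i
      bits <- 0
      # greedy walk: at each step take the smallest-index neighbor that lies
      # on some shortest path to j -> lexicographically minimal sequence
      while (cur != j) {
        rem <- pi_mat[cur, j]
        tot <- len[cur, ] + pi_mat[, j]
        cand <- which(tot <= rem + scale_tol(rem))
        cand <- cand[cand != cur]
        # guard against float drift between independently computed distances
        nxt <- if (length(cand)) min(cand) else which.min(tot)
        bits <- bits - logp[cur, nxt]
        cur <- nxt
      }
      si[i, j] <- bits
    }
  }
  nsi <- -(si + t(si)) / 2
  diag(nsi) <- 0
  nsi
}

#' Communicability
#'
#' Diffusive broadcasting: the weighted sum of all walks between node pairs,
#' computed as the matrix exponential of the strength-normalized weights
#' W' = S^(-1/2) W S^(-1/2) (s_i = node strength), which damps the influence
#' of high-strength hubs. `strength_norm = "literal"` instead uses
#' W'_ij = W_ij / (s_i s_j). Isolated nodes (zero strength) have their rows
#' and columns masked `NA` with a warning.
#'
#' @param weights symmetric non-negative weight matrix.
#' @param strength_norm `"sqrt"` (default) or `"literal"`.
#' @return N x N symmetric communicability matrix.
#' @export
communicability <- function(weights, strength_norm = c("sqrt", "literal")) {
  .check_weights(weights)
  strength_norm <- match.arg(strength_norm)
  s <- rowSums(weights)
  if (all(s == 0)) return(diag(nrow(weights))) # exp of the zero matrix
  iso <- s == 0
  if (any(iso)) {
    warn(sprintf("%d isolated node(s); their communicability is masked NA",
                 sum(iso)))
  }
  s_safe <- ifelse(iso, 1, s)
  wn <- if (strength_norm == "sqrt") {
    weights / sqrt(outer(s_safe, s_safe))
  } else {
    weights / outer(s_safe, s_safe)
  }
  eig <- eigen(wn, symmetric = TRUE)
  cmy <- eig$vectors %*% (exp(eig$values) * t(eig$vectors))
  cmy <- (cmy + t(cmy)) / 2
  if (any(iso)) {
    cmy[iso, ] <- NA_real_
    cmy[, iso] <- NA_real_
  }
  cmy
}

#' All three communication matrices for one network
#'
#' @param weights symmetric non-negative weight matrix.
#' @return List with `spe`, `nsi`, `cmy` matrices and a logical `valid` mask
#'   of off-diagonal pairs where all three are defined.
#' @export
communication_set <- function(weights) {
  spe <- shortest_path_efficiency(weights)
  nsi <- negative_search_information(weights)
  cmy <- communicability(weights)
  valid <- !is.na(nsi) & !is.na(cmy) & spe > 0
  diag(valid) <- FALSE
  list(spe = spe, nsi = nsi, cmy = cmy, valid = valid)
}

# ring lattice on n nodes with exactly m edges: fill neighbor rings of
# increasing circular distance; the last, partial ring is filled in node order
.ring_lattice_support <- function(n, m) {
  max_m <- n * (n - 1) / 2
  if (m > max_m) abort("too many edges for a simple graph")
  pairs_i <- integer(0); pairs_j <- integer(0)
  r <- 1
  while (length(pairs_i) < m) {
    if (r > n %/% 2) break
    if (2 * r == n) {
      i <- seq_len(n %/% 2) # antipodal ring has n/2 distinct pairs
    } else {
      i <- seq_len(n)
    }
    j <- ((i - 1 + r) %% n) + 1
    lo <- pmin(i, j); hi <- pmax(i, j)
    need <- m - length(pairs_i)
    take <- seq_len(min(need, length(lo)))
    pairs_i <- c(pairs_i, lo[take]); pairs_j <- c(pairs_j, hi[take])
    r <- r + 1
  }
  cbind(pairs_i, pairs_j)
}

# uniform random simple graph with exactly m edges
.random_support <- function(n, m) {
  n_pairs <- n * (n - 1) / 2
  picked <- sample.int(n_pairs, m)
  ut_idx <- which(.ut(n), arr.ind = TRUE)
  ut_idx[picked, , drop = FALSE]
}

.support_to_weights <- function(n, support, wvals) {
  w <- matrix(0, n, n)
  w[support] <- wvals
  w + t(w)
}

.global_efficiency <- function(weights) {
  spe <- shortest_path_efficiency(weights)
  mean(spe[.ut(nrow(spe))])
}

.global_communicability <- function(weights) {
  cmy <- suppressWarnings(communicability(weights))
  mean(cmy[.ut(nrow(cmy))], na.rm = TRUE)
}

#' Lattice/random-standardized communication morphospace point
#'
#' Places a network in a common communication space by scaling its mean
#' shortest-path efficiency and mean communicability against reference
#' ensembles of one-dimensional ring lattices and uniform random graphs
#' matched in size and edge count, each carrying a random permutation of the
#' network's own weight multiset:
#' `SPE_scaled = (E - <E_latt>) / (<E_rand> - <E_latt>)`,
#' so a lattice-like network sits near 0 and a random-like network near 1;
#' `CMY_scaled` analogously with mean communicability. The two axes span the
#' routing-to-diffusion spectrum of communication policies.
#'
#' @param weights symmetric non-negative weight matrix (connected network).
#' @param n_realizations reference graphs per ensemble (default 10).
#' @param seed integer seed.
#' @return A `morphospace_point`: list with `spe_scaled`, `cmy_scaled`, raw
#'   means and ensemble means.
#' @export
scaled_morphospace <- function(weights, n_realizations = 10L, seed = 1L) {
  .check_weights(weights)
  n <- nrow(weights)
  ut <- .ut(n)
  wvals <- weights[ut][weights[ut] > 0]
  m <- length(wvals)
  if (m < n - 1) abort("network too sparse for reference ensembles")
  e_spe <- .global_efficiency(weights)
  e_cmy <- .global_communicability(weights)
  latt_spe <- latt_cmy <- rand_spe <- rand_cmy <- numeric(n_realizations)
  latt_support <- .ring_lattice_support(n, m)
  for (r in seq_len(n_realizations)) {
    set.seed(.derive_seed(seed, r))
    wl <- .support_to_weights(n, latt_support, sample(wvals))
    wr <- .support_to_weights(n, .random_support(n, m), sample(wvals))
    latt_spe[r] <- .global_efficiency(wl)
    latt_cmy[r] <- .global_communicability(wl)
    rand_spe[r] <- .global_efficiency(wr)
    rand_cmy[r] <- .global_communicability(wr)
  }
  if (isTRUE(all.equal(mean(rand_spe), mean(latt_spe)))) {
    abort("degenerate references: lattice and random efficiencies coincide")
  }
  structure(list(
    spe_scaled = (e_spe - mean(latt_spe)) / (mean(rand_spe) - mean(latt_spe)),
    cmy_scaled = (e_cmy - mean(latt_cmy)) / (mean(rand_cmy) - mean(latt_cmy)),
    e_spe = e_spe, e_cmy = e_cmy,
    e_spe_latt = mean(latt_spe), e_spe_rand = mean(rand_spe),
    e_cmy_latt = mean(latt_cmy), e_cmy_rand = mean(rand_cmy),
    n_realizations = n_realizations
  ), class = "morphospace_point")
}

#' @export
print.morphospace_point <- function(x, ...) {
  cat(sprintf("<morphospace_point> SPE_scaled = %.3f, CMY_scaled = %.3f\n",
              x$spe_scaled, x$cmy_scaled))
  invisible(x)
}
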