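#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same nodes; 1 for
#' identical partitions (up to label permutation), ~0 for independent ones.
#' Used to score consensus partitions against planted ground truth.
#'
#' @param a,b label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) abort("partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1) # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
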