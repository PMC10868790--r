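#' Construct a connectome bundle
#'
#' A bundle is the atomic unit of a cohort: one animal's weighted anatomical
#' network together with its geometry and volumetric metadata. Weights are
#' streamline-count-derived and unitless; coordinates are node centroids in
#' voxel-like units; fiber lengths are defined only on the support of the
#' weight matrix (tracts exist only where streamlines were found).
#'
#' @param weights N x N symmetric, non-negative, zero-diagonal numeric matrix.
#' @param coordinates N x 3 numeric matrix of node centroid positions.
#' @param hemisphere character vector of `"L"`/`"R"` labels, one per node.
#' @param fiber_length sparse or dense N x N symmetric matrix of tract
#'   lengths; its support must be a subset of the weight support. Defaults to
#'   `NULL` (no tract lengths available).
#' @param metadata named list; conventionally carries `id`, `species`,
#'   `order`, `bv_cm3`, `gm_mm3`, `wm_mm3`.
#' @param planted_partition optional integer module labels (ground truth for
#'   synthetic bundles).
#' @return An object of class `connectome_bundle`.
#' @export
connectome_bundle <- function(weights, coordinates, hemisphere,
                              fiber_length = NULL, metadata = list(),
                              planted_partition = NULL) {
  .check_weights(weights)
  n <- nrow(weights)
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) != n || ncol(coordinates) != 3) {
    abort("`coordinates` must be an N x 3 matrix matching `weights`")
  }
  if (length(hemisphere) != n || !all(hemisphere %in% c("L", "R"))) {
    abort("`hemisphere` must be length N with values in {L, R}")
  }
  if (!is.null(fiber_length)) {
    fl <- as.matrix(fiber_length)
    if (!all(dim(fl) == n)) abort("`fiber_length` must be N x N")
    if (!isTRUE(all.equal(fl, t(fl), tolerance = 1e-10))) {
      abort("`fiber_length` violates symmetry")
    }
    if (any(fl[weights == 0] != 0)) {
      abort("`fiber_length` has entries outside the weight support")
    }
    fiber_length <- methods::as(methods::as(Matrix::Matrix(fl, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix")
  }
  if (!is.null(planted_partition)) {
    if (length(planted_partition) != n) {
      abort("`planted_partition` must have one label per node")
    }
    planted_partition <- as.integer(planted_partition)
  }
  structure(
    list(weights = weights, coordinates = coordinates,
         hemisphere = hemisphere, fiber_length = fiber_length,
         metadata = metadata, planted_partition = planted_partition),
    class = "connectome_bundle"
  )
}

#' @export
print.connectome_bundle <- function(x, ...) {
  n <- nrow(x$weights)
  e <- sum(x$weights[.ut(n)] > 0)
  cat(sprintf("<connectome_bundle> %s: %d nodes, %d edges (density %.3f)\n",
              x$metadata$id %||% "?", n, e, e / (n * (n - 1) / 2)))
  if (!is.null(x$metadata$bv_cm3)) {
    cat(sprintf("  brain volume %.4g cm^3, order %s\n",
                x$metadata$bv_cm3, x$metadata$order %||% "?"))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Euclidean distance matrix between node centroids
#'
#' Straight-line inter-node distance (ED), the geometric reference used for
#' all distance couplings; defined for every node pair, unlike tract length.
#'
#' @param bundle a [connectome_bundle()], or an N x 3 coordinate matrix.
#' @return N x N symmetric matrix of Euclidean distances.
#' @export
euclidean_distances <- function(bundle) {
  xyz <- if (inherits(bundle, "connectome_bundle")) bundle$coordinates
         else as.matrix(bundle)
  as.matrix(stats::dist(xyz))
}

#' Edge-cost matrix (weight times tract length)
#'
#' The material cost of a connection: edge weight multiplied by the length of
#' the tract linking its endpoints. Zero where no edge exists.
#'
#' @param bundle a [connectome_bundle()] with fiber lengths.
#' @return N x N symmetric cost matrix.
#' @export
connection_cost <- function(bundle) {
  stopifnot(inherits(bundle, "connectome_bundle"))
  if (is.null(bundle$fiber_length)) abort("bundle has no fiber lengths")
  bundle$weights * as.matrix(bundle$fiber_length)
}
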