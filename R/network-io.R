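#' Write a connectome bundle to disk
#'
#' Serializes one bundle as a directory of open interchange formats:
#' `weights.mtx` and `fiber_length.mtx` (MatrixMarket sparse, full
#' precision), `nodes.csv` (explicit `node_id` column, 0-based, plus
#' coordinates and hemisphere), and `metadata.json` (including the planted
#' partition when present). Bundle invariants are validated before writing.
#'
#' @param bundle a [connectome_bundle()].
#' @param path directory to create/populate.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "connectome_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  w <- Matrix::Matrix(bundle$weights, sparse = TRUE)
  Matrix::writeMM(methods::as(w, "generalMatrix"),
                  file.path(path, "weights.mtx"))
  if (!is.null(bundle$fiber_length)) {
    Matrix::writeMM(methods::as(bundle$fiber_length, "generalMatrix"),
                    file.path(path, "fiber_length.mtx"))
  }
  nodes <- data.frame(node_id = seq_len(nrow(bundle$weights)) - 1L,
                      x = bundle$coordinates[, 1],
                      y = bundle$coordinates[, 2],
                      z = bundle$coordinates[, 3],
                      hemisphere = bundle$hemisphere)
  utils::write.csv(nodes, file.path(path, "nodes.csv"), row.names = FALSE)
  meta <- bundle$metadata
  meta$planted_partition <- bundle$planted_partition
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a connectome bundle from disk
#'
#' Inverse of [write_bundle()]; the write/read round trip is the identity
#' (matrices bit-for-bit at the stored precision).
#'
#' @param path bundle directory.
#' @return A [connectome_bundle()].
#' @export
read_bundle <- function(path) {
  need <- file.path(path, c("weights.mtx", "nodes.csv", "metadata.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    abort(paste("missing bundle component file(s):",
                paste(basename(missing), collapse = ", ")))
  }
  w <- as.matrix(Matrix::readMM(file.path(path, "weights.mtx")))
  nodes <- utils::read.csv(file.path(path, "nodes.csv"))
  if (nrow(nodes) != nrow(w)) {
    abort(sprintf("shape mismatch: %d nodes in nodes.csv but %d x %d weights",
                  nrow(nodes), nrow(w), ncol(w)))
  }
  fl_path <- file.path(path, "fiber_length.mtx")
  fl <- if (file.exists(fl_path)) as.matrix(Matrix::readMM(fl_path)) else NULL
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  planted <- meta$planted_partition
  meta$planted_partition <- NULL
  connectome_bundle(
    weights = w,
    coordinates = as.matrix(nodes[, c("x", "y", "z")]),
    hemisphere = nodes$hemisphere,
    fiber_length = fl,
    metadata = meta,
    planted_partition = if (length(planted)) as.integer(planted) else NULL
  )
}

#' Write a cohort (bundles + manifest)
#'
#' Writes each bundle into `<dir>/<animal id>/` and a `manifest.json` listing
#' bundle paths in cohort order with a per-animal metadata echo, plus
#' `volumes.csv` with the volume table.
#'
#' @param cohort a `connectome_cohort` (see [generate_cohort()]).
#' @param dir output directory.
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "connectome_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(cohort$bundles)
  if (anyDuplicated(ids)) abort("bundle ids must be unique")
  for (id in ids) write_bundle(cohort$bundles[[id]], file.path(dir, id))
  manifest <- list(
    bundles = lapply(ids, function(id) {
      list(id = id, path = id,
           metadata = cohort$bundles[[id]]$metadata)
    })
  )
  utils::write.csv(cohort$volumes, file.path(dir, "volumes.csv"),
                   row.names = FALSE)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(mf)
}

#' Read a cohort from a manifest
#'
#' @param dir cohort directory containing `manifest.json` (as written by
#'   [write_cohort()]).
#' @return A `connectome_cohort`.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) abort("manifest.json not found")
  manifest <- jsonlite::read_json(mf, simplifyVector = FALSE)
  bundles <- list()
  for (entry in manifest$bundles) {
    bpath <- file.path(dir, entry$path)
    if (!dir.exists(bpath)) {
      abort(sprintf("manifest references missing bundle '%s'", entry$path))
    }
    bundles[[entry$id]] <- read_bundle(bpath)
  }
  vol_path <- file.path(dir, "volumes.csv")
  volumes <- if (file.exists(vol_path)) {
    tibble::as_tibble(utils::read.csv(vol_path))
  } else NULL
  structure(list(volumes = volumes, bundles = bundles, spec = NULL),
            class = "connectome_cohort")
}

#' Where to obtain the deposited mammalian connectome dataset
#'
#' The analyses in this package were designed around a publicly deposited
#' cohort of diffusion-MRI-derived mammalian connectomes. This helper
#' documents the deposit and, on request, downloads the archive; no other
#' function or test depends on it, and the archive's internal layout must
#' be mapped to bundle directories by the user (see [write_bundle()] for
#' the expected layout).
#'
#' @param dest directory to download into (created if needed).
#' @param download if `TRUE`, fetch the archive record page via
#'   `utils::download.file`; default `FALSE` (just return the reference).
#' @return List with the deposit `doi` and `url` (invisibly when
#'   downloading).
#' @export
fetch_deposited_dataset <- function(dest = ".", download = FALSE) {
  info <- list(doi = "10.5281/zenodo.10372945",
               url = "https://doi.org/10.5281/zenodo.10372945")
  if (download) {
    dir.create(dest, recursive = TRUE, showWarnings = FALSE)
    utils::download.file(info$url, file.path(dest, "mami_record.html"),
                         mode = "wb")
    return(invisible(info))
  }
  info
}
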