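#' Specify a synthetic mammalian-like cohort
#'
#' Collects every knob of the synthetic cohort generator in one validated
#' object. Defaults emulate the structure of the empirical mammalian imaging
#' cohort the analysis was designed for: ~200 animals with 200-node
#' connectomes (100 per hemisphere), brain volumes log-uniform over
#' \[0.0842, 1597.3\] cm^3, grey- and white-matter volumes following the
#' allometric power laws log10 GM = 0.98 log10 BV + 0.013 and
#' log10 WM = 1.16 log10 GM - 1.45 (volumes in mm^3), and distance-dependent
#' modular connectivity whose spatial penalty tightens with brain volume so
#' that larger brains have more spatially compact modules.
#'
#' @param n_animals number of animals in the cohort.
#' @param n_nodes nodes per connectome; must be even (half per hemisphere).
#' @param volume_range length-2 positive increasing brain-volume range, cm^3.
#' @param gm_slope,gm_intercept log10-space power law of GM volume on brain
#'   volume (mm^3).
#' @param wm_slope,wm_intercept log10-space power law of WM volume on GM
#'   volume (mm^3).
#' @param noise_sd sd of lognormal multiplicative noise on the volume laws,
#'   in log10 space; 0 puts the table exactly on the laws.
#' @param n_modules planted spatial modules per hemisphere (>= 2 total per
#'   brain is guaranteed since both hemispheres carry their own modules).
#' @param spatial_decay_base distance-penalty scale lambda at the geometric
#'   mid-volume, in normalized (brain-size-relative) distance units.
#' @param spatial_decay_volume_coupling exponent with which lambda shrinks as
#'   volume grows: lambda(V) = base * (V / V_mid)^(-coupling). Positive values
#'   plant the "larger brains are more spatially constrained" trend.
#' @param within_module_boost multiplier added to the connection probability
#'   of same-module node pairs (probability factor `1 + boost`).
#' @param weight_noise_sd sd (natural-log space) of the lognormal jitter on
#'   edge weights; the default 1.0 reproduces the orders-of-magnitude spread
#'   of streamline-count weights, so distance explains much but not all of
#'   an edge's weight.
#' @param target_density fraction of possible edges to realize, in (0, 1].
#' @param fiber_length_factor tract length as a multiple of Euclidean
#'   distance on existing edges (tracts are never shorter than straight
#'   lines).
#' @param seed integer master seed for the cohort.
#' @return A `cohort_spec` object (validated list).
#' @export
cohort_spec <- function(n_animals = 200L,
                        n_nodes = 200L,
                        volume_range = c(0.0842, 1597.3),
                        gm_slope = 0.98, gm_intercept = 0.013,
                        wm_slope = 1.16, wm_intercept = -1.45,
                        noise_sd = 0.05,
                        n_modules = 4L,
                        spatial_decay_base = 0.4,
                        spatial_decay_volume_coupling = 0.2,
                        within_module_boost = 3,
                        weight_noise_sd = 1.0,
                        target_density = 0.2,
                        fiber_length_factor = 1.2,
                        seed = 42L) {
  spec <- list(n_animals = as.integer(n_animals), n_nodes = as.integer(n_nodes),
               volume_range = as.numeric(volume_range),
               gm_slope = gm_slope, gm_intercept = gm_intercept,
               wm_slope = wm_slope, wm_intercept = wm_intercept,
               noise_sd = noise_sd, n_modules = as.integer(n_modules),
               spatial_decay_base = spatial_decay_base,
               spatial_decay_volume_coupling = spatial_decay_volume_coupling,
               within_module_boost = within_module_boost,
               weight_noise_sd = weight_noise_sd,
               target_density = target_density,
               fiber_length_factor = fiber_length_factor,
               seed = as.integer(seed))
  if (spec$n_animals < 1) abort("`n_animals` must be positive")
  if (spec$n_nodes < 4 || spec$n_nodes %% 2 != 0) {
    abort("`n_nodes` must be even and >= 4")
  }
  if (length(spec$volume_range) != 2 || any(spec$volume_range <= 0) ||
      diff(spec$volume_range) <= 0) {
    abort("`volume_range` must be positive and increasing")
  }
  if (spec$noise_sd < 0) abort("`noise_sd` must be non-negative")
  if (spec$n_modules < 2) abort("`n_modules` must be >= 2")
  if (spec$target_density <= 0 || spec$target_density > 1) {
    abort("`target_density` must be in (0, 1]")
  }
  if (spec$within_module_boost < 0) abort("`within_module_boost` must be >= 0")
  if (spec$weight_noise_sd < 0) abort("`weight_noise_sd` must be >= 0")
  if (spec$spatial_decay_base <= 0) abort("`spatial_decay_base` must be > 0")
  if (spec$fiber_length_factor < 1) abort("`fiber_length_factor` must be >= 1")
  structure(spec, class = "cohort_spec")
}

# 12 neutral clade labels, noisily ordered by volume so that taxonomy and
# volume are collinear but overlapping, as in real mammalian cohorts
.assign_orders <- function(log_bv, n_orders = 12L) {
  score <- log_bv + rnorm(length(log_bv), sd = 0.35)
  labs <- sprintf("clade_%02d", seq_len(n_orders))
  if (length(log_bv) < n_orders) {
    return(labs[rank(score, ties.method = "first")])
  }
  edges <- quantile(score, probs = seq(0, 1, length.out = n_orders + 1))
  edges[1] <- -Inf; edges[n_orders + 1] <- Inf
  labs[cut(score, breaks = edges, labels = FALSE, include.lowest = TRUE)]
}

#' Generate a volume table
#'
#' Samples per-animal brain volumes log-uniformly over the configured range
#' and derives grey- and white-matter volumes from the allometric power laws
#' (with lognormal noise), plus a taxonomic-order label correlated with
#' volume.
#'
#' @param spec a [cohort_spec()].
#' @return A tibble with columns `animal_id`, `species`, `order`, `bv_cm3`,
#'   `bv_mm3`, `gm_mm3`, `wm_mm3`, and attribute `volume_unit = "mm3"` on the
#'   law columns.
#' @export
generate_volume_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(.derive_seed(spec$seed, 0L))
  n <- spec$n_animals
  log_bv_cm3 <- runif(n, log10(spec$volume_range[1]), log10(spec$volume_range[2]))
  bv_cm3 <- 10^log_bv_cm3
  bv_mm3 <- bv_cm3 * 1000
  log_gm <- spec$gm_slope * log10(bv_mm3) + spec$gm_intercept +
    rnorm(n, sd = spec$noise_sd)
  log_wm <- spec$wm_slope * log_gm + spec$wm_intercept +
    rnorm(n, sd = spec$noise_sd)
  tibble(
    animal_id = sprintf("animal_%03d", seq_len(n)),
    species = sprintf("species_%03d", seq_len(n)),
    order = .assign_orders(log10(bv_mm3)),
    bv_cm3 = bv_cm3,
    bv_mm3 = bv_mm3,
    gm_mm3 = 10^log_gm,
    wm_mm3 = 10^log_wm
  )
}

# distance-penalty scale for a given brain volume (cm^3)
.lambda_of_volume <- function(volume, spec) {
  v_mid <- sqrt(prod(spec$volume_range))
  spec$spatial_decay_base *
    (volume / v_mid)^(-spec$spatial_decay_volume_coupling)
}

#' Generate one spatially embedded modular connectome
#'
#' Places `n_nodes/2` nodes per hemisphere in mirrored point clouds scaled by
#' `volume^(1/3)`, plants `n_modules` spatial modules per hemisphere, and
#' draws edges with probability proportional to
#' `exp(-d_ij / lambda(volume)) * (1 + within_module_boost * same_module)`,
#' sampling exactly enough edges to hit `target_density`. Edge weights decay
#' with distance (with lognormal jitter); fiber lengths are a supra-Euclidean
#' multiple of the straight-line distance on existing edges. The planted
#' partition is stored as ground truth.
#'
#' @param volume brain volume in cm^3.
#' @param spec a [cohort_spec()].
#' @param seed integer seed for this animal.
#' @param metadata optional named list merged into the bundle metadata.
#' @param max_tries regenerate a disconnected draw up to this many times.
#' @return A [connectome_bundle()].
#' @export
generate_connectome <- function(volume, spec, seed,
                                metadata = list(), max_tries = 10L) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (volume <= 0) abort("`volume` must be positive")
  n <- spec$n_nodes
  half <- n %/% 2
  lambda <- .lambda_of_volume(volume, spec)
  for (try in seq_len(max_tries)) {
    set.seed(.derive_seed(seed, try - 1L))
    # left-hemisphere module centers and node cloud in unit scale; right is
    # the mirror image across the x = 0 midline
    centers <- cbind(runif(spec$n_modules, -1, -0.25),
                     runif(spec$n_modules, -0.75, 0.75),
                     runif(spec$n_modules, -0.75, 0.75))
    mod_left <- rep(seq_len(spec$n_modules), length.out = half)
    # module spatial compactness follows the distance-penalty scale: larger
    # brains get geometrically tighter modules, smaller brains diffuse ones
    scatter <- 0.55 * lambda
    xyz_left <- centers[mod_left, , drop = FALSE] +
      matrix(rnorm(half * 3, sd = scatter), half, 3)
    xyz_right <- xyz_left %*% diag(c(-1, 1, 1))
    xyz <- rbind(xyz_left, xyz_right)
    planted <- c(mod_left, mod_left + spec$n_modules)

    d <- as.matrix(stats::dist(xyz))
    same <- outer(planted, planted, "==")
    ut <- .ut(n)
    score <- exp(-d[ut] / lambda) *
      (1 + spec$within_module_boost * same[ut])
    n_pairs <- n * (n - 1) / 2
    n_edges <- max(n - 1L, round(spec$target_density * n_pairs))
    picked <- sample.int(n_pairs, n_edges, prob = score)

    w <- matrix(0, n, n)
    wvals <- exp(-d[ut][picked] / lambda +
                   rnorm(n_edges, sd = spec$weight_noise_sd))
    w[ut][picked] <- wvals
    w <- w + t(w)

    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    if (igraph::is_connected(g)) {
      coords <- xyz * volume^(1 / 3)
      ed <- as.matrix(stats::dist(coords))
      fl <- ifelse(w > 0, spec$fiber_length_factor * ed, 0)
      hemi <- rep(c("L", "R"), each = half)
      meta <- utils::modifyList(
        list(id = NULL, bv_cm3 = volume, lambda = lambda, seed = seed),
        metadata)
      return(connectome_bundle(w, coords, hemi, fiber_length = fl,
                               metadata = meta,
                               planted_partition = planted))
    }
  }
  abort(sprintf(
    "connectome disconnected after %d attempts (volume %.4g, density %.3g)",
    max_tries, volume, spec$target_density))
}

#' Generate a full synthetic cohort
#'
#' One volume-table row and one connectome per animal. Every animal uses its
#' own seed derived from `(spec$seed, animal index)`, so cohorts are
#' reproducible and individual animals can be regenerated independently.
#'
#' @param spec a [cohort_spec()].
#' @return A `connectome_cohort`: list with `volumes` (tibble from
#'   [generate_volume_table()]) and `bundles` (named list of
#'   [connectome_bundle()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  volumes <- generate_volume_table(spec)
  bundles <- purrr::map(seq_len(spec$n_animals), function(i) {
    row <- volumes[i, ]
    generate_connectome(
      row$bv_cm3, spec, seed = .derive_seed(spec$seed, i),
      metadata = list(id = row$animal_id, species = row$species,
                      order = row$order, bv_cm3 = row$bv_cm3,
                      gm_mm3 = row$gm_mm3, wm_mm3 = row$wm_mm3))
  })
  names(bundles) <- volumes$animal_id
  structure(list(volumes = volumes, bundles = bundles, spec = spec),
            class = "connectome_cohort")
}

#' @export
print.connectome_cohort <- function(x, ...) {
  cat(sprintf("<connectome_cohort> %d animals, %d nodes each\n",
              length(x$bundles), x$spec$n_nodes))
  invisible(x)
}

#' Weight-jittered replicate networks of one bundle
#'
#' Emulates the within-animal variability of repeated stochastic
#' parcellations by multiplying each edge weight by lognormal noise;
#' optionally rewires a fraction of edges. Used to exercise
#' representative-network (centroid) selection.
#'
#' @param bundle a [connectome_bundle()].
#' @param n number of replicates.
#' @param jitter_sd sd of the lognormal weight jitter (log space).
#' @param rewire_frac fraction of edges randomly relocated per replicate.
#' @param seed integer seed.
#' @return List of `n` weight matrices.
#' @export
jitter_replicates <- function(bundle, n = 10L, jitter_sd = 0.1,
                              rewire_frac = 0, seed = 1L) {
  w0 <- if (inherits(bundle, "connectome_bundle")) bundle$weights else bundle
  nn <- nrow(w0)
  ut <- .ut(nn)
  purrr::map(seq_len(n), function(k) {
    set.seed(.derive_seed(seed, k))
    w <- matrix(0, nn, nn)
    vals <- w0[ut]
    pos <- which(vals > 0)
    vals[pos] <- vals[pos] * exp(rnorm(length(pos), sd = jitter_sd))
    if (rewire_frac > 0) {
      n_move <- ceiling(rewire_frac * length(pos))
      from <- sample(pos, n_move)
      to <- sample(setdiff(seq_along(vals), pos), n_move)
      vals[to] <- vals[from]
      vals[from] <- 0
    }
    w[ut] <- vals
    w + t(w)
  })
}
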