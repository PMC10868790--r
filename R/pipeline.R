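#' Configuration of a cohort analysis run
#'
#' Bundles every tunable of the per-animal and cross-animal pipeline so that
#' a run is fully determined by (cohort, config).
#'
#' @param density `"none"` or a numeric density in (0, 1\] to which every
#'   network is thresholded before analysis (backbone-preserving).
#' @param n_gamma resolutions per sweep step of the multiresolution ensemble.
#' @param coarse_range step-1 resolution range.
#' @param gamma_mode `"joint"` (default) intersects the per-animal resolution
#'   brackets so one \[gamma_L, gamma_H\] range — producing 2..N/2 modules
#'   for every animal — serves the whole cohort; `"per_animal"` brackets each
#'   animal independently.
#' @param consensus_restarts Louvain restarts for the consensus step.
#' @param morpho_realizations reference graphs per morphospace ensemble.
#' @param n_boot bootstrap iterations for the volume scaling fits.
#' @param n_null Mantel-permutation draws per animal used to attach a
#'   null-model p-value to the agreement-weight coupling (0 disables the
#'   null comparison).
#' @param max_fail_frac run fails if more than this fraction of animals
#'   error out.
#' @param seed integer seed for all per-animal randomness.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(density = "none",
                            n_gamma = 100L,
                            coarse_range = c(0.01, 10),
                            gamma_mode = c("joint", "per_animal"),
                            consensus_restarts = 100L,
                            morpho_realizations = 10L,
                            n_boot = 10000L,
                            n_null = 0L,
                            max_fail_frac = 0.1,
                            seed = 1L) {
  if (!identical(density, "none")) {
    density <- as.numeric(density)
    if (is.na(density) || density <= 0 || density > 1) {
      abort("`density` must be \"none\" or a fraction in (0, 1]")
    }
  }
  gamma_mode <- match.arg(gamma_mode)
  structure(list(density = density, n_gamma = as.integer(n_gamma),
                 coarse_range = coarse_range, gamma_mode = gamma_mode,
                 consensus_restarts = as.integer(consensus_restarts),
                 morpho_realizations = as.integer(morpho_realizations),
                 n_boot = as.integer(n_boot), n_null = as.integer(n_null),
                 max_fail_frac = max_fail_frac, seed = as.integer(seed)),
            class = "analysis_config")
}

#' Per-animal feature row
#'
#' Runs the full single-animal pipeline: optional density thresholding, the
#' multiresolution ensemble, co-classification matrix and consensus
#' partition, module features, the three communication matrices, the
#' morphospace point, and all Fisher-z-transformed node-pair couplings. Pairs
#' without an edge contribute weight 0 and cost 0 to the CC couplings;
#' Euclidean distance is defined for every pair.
#'
#' @param bundle a [connectome_bundle()].
#' @param config an [analysis_config()].
#' @param seed per-animal seed (defaults to the config seed).
#' @param gamma_range optional shared \[gamma_L, gamma_H\] resolution range
#'   (joint cohort bracketing); when `NULL` the animal is bracketed on its
#'   own.
#' @return One-row tibble of scalar features.
#' @export
analyze_bundle <- function(bundle, config = analysis_config(), seed = NULL,
                           gamma_range = NULL) {
  stopifnot(inherits(bundle, "connectome_bundle"))
  seed <- seed %||% config$seed
  w <- bundle$weights
  if (!identical(config$density, "none")) {
    w <- threshold_to_density(w, config$density)
  }
  ed <- euclidean_distances(bundle)
  cost <- if (!is.null(bundle$fiber_length)) {
    w * as.matrix(bundle$fiber_length)
  } else NULL

  ens <- mrcc_ensemble(w, n_gamma = config$n_gamma,
                       coarse_range = config$coarse_range,
                       seed = .derive_seed(seed, 1L),
                       gamma_range = gamma_range)
  cc <- coclassification_matrix(ens)
  consensus <- consensus_from_cc(cc, seed = .derive_seed(seed, 2L),
                                 n_restarts = config$consensus_restarts)
  feats <- partition_features(w, ed, consensus)
  ih <- interhemispheric_cc(cc, bundle$hemisphere)

  comm <- communication_set(w)
  morpho <- scaled_morphospace(w, n_realizations = config$morpho_realizations,
                               seed = .derive_seed(seed, 3L))

  couple <- function(a, b, mask = NULL) {
    suppressWarnings(pairwise_coupling(a, b, mask))
  }
  # Mantel-null exceedance of the agreement-weight coupling: fraction of
  # node-permuted CC draws with |rho| at least the empirical one
  mantel_p <- NA_real_
  if (config$n_null > 0) {
    rho_emp <- couple(cc, w)
    null_rho <- vapply(
      permute_cc_mantel(cc, n_perm = config$n_null,
                        seed = .derive_seed(seed, 4L)),
      function(p) couple(p, w), numeric(1))
    mantel_p <- (1 + sum(abs(null_rho) >= abs(rho_emp))) / (config$n_null + 1)
  }
  m <- bundle$metadata
  tibble(
    animal_id = m$id %||% NA_character_,
    order = m$order %||% NA_character_,
    bv_cm3 = m$bv_cm3 %||% NA_real_,
    gm_mm3 = m$gm_mm3 %||% NA_real_,
    wm_mm3 = m$wm_mm3 %||% NA_real_,
    rho_cc_weight = couple(cc, w),
    rho_cc_cost = if (is.null(cost)) NA_real_ else couple(cc, cost),
    rho_cc_ed = couple(cc, ed),
    rho_ed_spe = couple(ed, comm$spe, comm$valid),
    rho_ed_nsi = couple(ed, comm$nsi, comm$valid),
    rho_ed_cmy = couple(ed, comm$cmy, comm$valid),
    rho_cc_spe = couple(cc, comm$spe, comm$valid),
    rho_cc_nsi = couple(cc, comm$nsi, comm$valid),
    rho_cc_cmy = couple(cc, comm$cmy, comm$valid),
    imd = feats$imd,
    longdist_fraction = feats$longdist_fraction,
    n_modules = feats$n_modules,
    interhemispheric_cc = ih,
    spe_scaled = morpho$spe_scaled,
    cmy_scaled = morpho$cmy_scaled,
    mantel_p_cc_weight = mantel_p
  )
}

# features whose per-animal value is a correlation (Fisher-z'd before the
# cross-animal correlation with volume) vs. plain scalar features
.coupling_features <- c("rho_cc_weight", "rho_cc_cost", "rho_cc_ed",
                        "rho_ed_spe", "rho_ed_nsi", "rho_ed_cmy",
                        "rho_cc_spe", "rho_cc_nsi", "rho_cc_cmy")
.scalar_features <- c("imd", "longdist_fraction", "interhemispheric_cc",
                      "spe_scaled", "cmy_scaled")

#' Cross-animal analysis of a cohort
#'
#' Computes the per-animal feature table (see [analyze_bundle()]; failures
#' are isolated and reported, the run fails only if more than
#' `max_fail_frac` of animals error), then the cross-animal statistics: the
#' Spearman correlation panel of every feature against brain volume
#' (couplings Fisher-z-transformed first), optional partial correlations
#' controlling for a covariate, and bootstrapped GM/WM/BV allometric scaling
#' fits when the cohort carries a volume table.
#'
#' @param cohort a `connectome_cohort` (from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config an [analysis_config()].
#' @param partial_covariate optional feature-table column name (e.g.
#'   `"order"`) to control for in an additional partial-correlation panel.
#' @return A `cohort_analysis`: list with `features` (tibble), `panel`
#'   (tibble of feature/rho/p), `partial_panel` (or `NULL`), `fits` (named
#'   list of `scaling_fit`), `failures`, `config`.
#' @export
run_cohort_analysis <- function(cohort, config = analysis_config(),
                                partial_covariate = NULL) {
  stopifnot(inherits(cohort, "connectome_cohort"))
  ids <- names(cohort$bundles)
  gamma_range <- if (config$gamma_mode == "joint") {
    joint_gamma_bracket(cohort, config)
  } else NULL
  rows <- vector("list", length(ids))
  failures <- character(0)
  for (i in seq_along(ids)) {
    rows[[i]] <- tryCatch(
      analyze_bundle(cohort$bundles[[i]], config,
                     seed = .derive_seed(config$seed, i),
                     gamma_range = gamma_range),
      error = function(e) {
        failures <<- c(failures,
                       sprintf("%s: %s", ids[i], conditionMessage(e)))
        NULL
      })
  }
  if (length(failures) > config$max_fail_frac * length(ids)) {
    abort(paste0("too many per-animal failures:\n",
                 paste(failures, collapse = "\n")))
  }
  features <- bind_rows(rows)
  if (nrow(features) == 0) abort("no animal analyzed successfully")

  panel <- cohort_correlation_panel(features)
  partial_panel <- if (!is.null(partial_covariate)) {
    cohort_correlation_panel(features, partial_covariate = partial_covariate)
  } else NULL

  fits <- list()
  if (all(c("gm_mm3", "wm_mm3", "bv_cm3") %in% names(features)) &&
      !anyNA(features$gm_mm3) && nrow(features) >= 5) {
    fits$wm_gm <- bootstrap_loglog_fit(features$gm_mm3, features$wm_mm3,
                                       n_boot = config$n_boot,
                                       seed = .derive_seed(config$seed, 9001L))
    fits$gm_bv <- bootstrap_loglog_fit(features$bv_cm3 * 1000, features$gm_mm3,
                                       n_boot = config$n_boot,
                                       seed = .derive_seed(config$seed, 9002L))
  }
  structure(list(features = features, panel = panel,
                 partial_panel = partial_panel, fits = fits,
                 failures = failures, config = config),
            class = "cohort_analysis")
}

#' Joint resolution bracket for a cohort
#'
#' Intersects the per-animal resolution brackets: the returned `gamma_l` is
#' the largest per-animal lower bound and `gamma_h` the smallest per-animal
#' upper bound, so the shared range yields between 2 and N/2 modules for
#' every animal. Falls back to the union midpoint if the intersection is
#' empty (warns).
#'
#' @param cohort a `connectome_cohort`.
#' @param config an [analysis_config()].
#' @return Length-2 numeric `c(gamma_l, gamma_h)`.
#' @export
joint_gamma_bracket <- function(cohort, config = analysis_config()) {
  ids <- names(cohort$bundles)
  brackets <- purrr::map(seq_along(ids), function(i) {
    w <- cohort$bundles[[i]]$weights
    if (!identical(config$density, "none")) {
      w <- threshold_to_density(w, config$density)
    }
    mrcc_bracket(w, n_gamma = config$n_gamma,
                 coarse_range = config$coarse_range,
                 seed = .derive_seed(.derive_seed(config$seed, i), 1L))
  })
  gl <- max(vapply(brackets, `[[`, numeric(1), "gamma_l"))
  gh <- min(vapply(brackets, `[[`, numeric(1), "gamma_h"))
  if (gh < gl) {
    warn("empty joint resolution bracket; falling back to the union range")
    gl <- min(vapply(brackets, `[[`, numeric(1), "gamma_l"))
    gh <- max(vapply(brackets, `[[`, numeric(1), "gamma_h"))
  }
  c(gl, gh)
}

#' Feature-versus-volume correlation panel
#'
#' One row per feature: Spearman rho (and p) between brain volume and the
#' feature across animals. Coupling features are Fisher-z-transformed first;
#' rank correlations are invariant to this monotone transform, so the
#' transform matters only for parametric follow-ups.
#'
#' @param features feature table from [run_cohort_analysis()] /
#'   [analyze_bundle()].
#' @param partial_covariate optional column name to residualize on (partial
#'   rank correlation).
#' @return Tibble with `feature`, `rho`, `p`, `n`.
#' @export
cohort_correlation_panel <- function(features, partial_covariate = NULL) {
  if (nrow(features) == 0) abort("empty feature table")
  feats <- c(.coupling_features, .scalar_features)
  feats <- feats[feats %in% names(features)]
  bv <- features$bv_cm3
  rows <- purrr::map(feats, function(f) {
    x <- features[[f]]
    if (f %in% .coupling_features) x <- fisher_z(x)
    ok <- is.finite(x) & is.finite(bv)
    res <- if (sum(ok) < 3) {
      list(rho = NA_real_, p = NA_real_)
    } else if (is.null(partial_covariate)) {
      suppressWarnings(rank_correlation(bv[ok], x[ok]))
    } else {
      # degenerate covariate encodings (e.g. one order per animal) yield an
      # undefined partial correlation for this panel row, not a failed run
      tryCatch(
        suppressWarnings(partial_rank_correlation(
          bv[ok], x[ok], features[ok, partial_covariate, drop = FALSE])),
        error = function(e) list(rho = NA_real_, p = NA_real_))
    }
    tibble(feature = f, rho = res$rho, p = res$p, n = sum(ok))
  })
  bind_rows(rows)
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(sprintf("<cohort_analysis> %d animals (%d failures)\n",
              nrow(x$features), length(x$failures)))
  print(x$panel, n = Inf)
  invisible(x)
}

#' Human-readable report of a cohort analysis
#'
#' @param analysis a `cohort_analysis`.
#' @param digits significant digits in the formatted numbers.
#' @return Character vector of report lines (also printed).
#' @export
summarize_results <- function(analysis, digits = 3) {
  stopifnot(inherits(analysis, "cohort_analysis"))
  if (nrow(analysis$features) == 0) abort("empty feature table")
  fmt <- function(v) formatC(v, digits = digits, format = "g")
  lines <- c(sprintf("Cohort analysis: %d animals, %d failed",
                     nrow(analysis$features), length(analysis$failures)))
  for (nm in names(analysis$fits)) {
    f <- analysis$fits[[nm]]
    lines <- c(lines, sprintf(
      "Scaling law %s: slope %s +/- %s, intercept %s +/- %s",
      nm, fmt(f$slope_mean), fmt(f$slope_sd),
      fmt(f$intercept_mean), fmt(f$intercept_sd)))
  }
  lines <- c(lines, "Feature vs brain volume (Spearman):")
  p <- analysis$panel
  lines <- c(lines, sprintf("  %-22s rho = %8s  p = %s",
                            p$feature, fmt(p$rho), fmt(p$p)))
  if ("mantel_p_cc_weight" %in% names(analysis$features) &&
      any(is.finite(analysis$features$mantel_p_cc_weight))) {
    mp <- analysis$features$mantel_p_cc_weight
    lines <- c(lines, sprintf(
      "Null model (Mantel permutation of CC): max per-animal p for rho(CC,weight) = %s over %d animals",
      fmt(max(mp, na.rm = TRUE)), sum(is.finite(mp))))
  }
  if (!is.null(analysis$partial_panel)) {
    pp <- analysis$partial_panel
    lines <- c(lines, "Partial correlations (covariate-controlled):")
    lines <- c(lines, sprintf("  %-22s rho = %8s  p = %s",
                              pp$feature, fmt(pp$rho), fmt(pp$p)))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
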