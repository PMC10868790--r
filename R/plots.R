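#' Plot an allometric scaling law
#'
#' Log-log scatter of two volume columns with the bootstrapped power-law fit
#' overlaid.
#'
#' @param volumes data frame with the two columns (e.g. a volume table).
#' @param x,y column names (strings) of the predictor and response volumes.
#' @param fit optional `scaling_fit`; computed (1,000 iterations) if missing.
#' @return A ggplot object.
#' @export
plot_scaling_law <- function(volumes, x = "gm_mm3", y = "wm_mm3", fit = NULL) {
  if (is.null(fit)) {
    fit <- bootstrap_loglog_fit(volumes[[x]], volumes[[y]], n_boot = 1000L)
  }
  df <- tibble(lx = log10(volumes[[x]]), ly = log10(volumes[[y]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lx, y = .data$ly)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = fit$slope_mean,
                         intercept = fit$intercept_mean,
                         colour = "firebrick") +
    ggplot2::labs(
      x = paste0("log10 ", x), y = paste0("log10 ", y),
      title = sprintf("log10 %s = (%.3f ± %.3f) log10 %s + (%.3f ± %.3f)",
                      y, fit$slope_mean, fit$slope_sd, x,
                      fit$intercept_mean, fit$intercept_sd)) +
    ggplot2::theme_minimal()
}

#' Plot one feature against brain volume
#'
#' @param features feature table from [run_cohort_analysis()].
#' @param feature feature column name.
#' @return A ggplot object (volume on a log axis, colored by order).
#' @export
plot_volume_trend <- function(features, feature = "rho_cc_ed") {
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data$bv_cm3, y = .data[[feature]],
                               colour = .data$order)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "brain volume (cm³, log scale)", y = feature) +
    ggplot2::theme_minimal()
}

#' Plot the communication morphospace
#'
#' Routing efficiency (SPE scaled) against diffusion efficiency (CMY
#' scaled), points colored by log brain volume.
#'
#' @param features feature table from [run_cohort_analysis()].
#' @return A ggplot object.
#' @export
plot_morphospace <- function(features) {
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data$cmy_scaled, y = .data$spe_scaled,
                               colour = log10(.data$bv_cm3))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c(name = "log10 BV (cm³)") +
    ggplot2::labs(x = "diffusion efficiency (CMY scaled)",
                  y = "routing efficiency (SPE scaled)") +
    ggplot2::theme_minimal()
}

#' Autoplot a cohort analysis: the feature-versus-volume panel
#'
#' Bar panel of the Spearman correlation between each feature and brain
#' volume, annotated with significance.
#'
#' @param object a `cohort_analysis`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_analysis <- function(object, ...) {
  p <- object$panel
  p$sig <- ifelse(!is.na(p$p) & p$p < 0.05, "p < 0.05", "n.s.")
  ggplot2::ggplot(p, ggplot2::aes(x = stats::reorder(.data$feature, .data$rho),
                                  y = .data$rho, fill = .data$sig)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Spearman rho vs brain volume",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
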