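#' Spearman coupling between two node-pair matrices
#'
#' Rank correlation over the masked upper-triangle entries of two node-pair
#' matrices (for instance agreement vs. weight, or distance vs. a
#' communication matrix). The diagonal is always excluded; pass a logical
#' `mask` to exclude further pairs (e.g., pairs where a measure is
#' undefined).
#'
#' @param a,b numeric matrices of identical dimension.
#' @param mask optional logical matrix of valid pairs.
#' @return Spearman rho (scalar); `NA` with a warning if either input is
#'   constant over the valid pairs.
#' @export
pairwise_coupling <- function(a, b, mask = NULL) {
  if (!all(dim(a) == dim(b))) abort("matrices must have identical dimensions")
  n <- nrow(a)
  sel <- .ut(n)
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(a))) abort("`mask` dimension mismatch")
    sel <- sel & mask
  }
  x <- a[sel]; y <- b[sel]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("fewer than 3 valid pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant input: coupling undefined")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Bootstrapped log-log power-law fit
#'
#' Fits `log10 y = slope * log10 x + intercept` by ordinary least squares,
#' bootstrapped over draws of `floor(frac * n)` observations (sampled with
#' replacement), which tempers the influence of outliers and of species
#' represented by multiple animals. Reports the mean and standard deviation
#' of slope and intercept over iterations; with `frac = 0.9` the sd is close
#' to the standard error of the full-sample estimate.
#'
#' @param x,y positive numeric vectors (e.g., volumes).
#' @param frac subsample fraction (default 0.9).
#' @param n_boot iterations (default 10000).
#' @param seed integer seed.
#' @return A `scaling_fit` object; see [tidy.scaling_fit()] and
#'   [glance.scaling_fit()].
#' @export
bootstrap_loglog_fit <- function(x, y, frac = 0.9, n_boot = 10000L, seed = 1L) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (any(x <= 0) || any(y <= 0)) abort("log-log fit requires positive values")
  n <- length(x)
  if (n < 5) abort("need at least 5 observations")
  if (frac <= 0 || frac > 1) abort("`frac` must be in (0, 1]")
  lx <- log10(x); ly <- log10(y)
  k <- max(3L, floor(frac * n))
  set.seed(.derive_seed(seed, 0L))
  slopes <- numeric(n_boot); inters <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, k, replace = TRUE)
    xs <- lx[idx]; ys <- ly[idx]
    sl <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
    slopes[b] <- sl
    inters[b] <- mean(ys) - sl * mean(xs)
  }
  structure(list(slope_mean = mean(slopes), slope_sd = sd(slopes),
                 intercept_mean = mean(inters), intercept_sd = sd(inters),
                 n = n, n_boot = n_boot, frac = frac, seed = seed),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf(
    "<scaling_fit> log10 y = (%.3f +/- %.4f) log10 x + (%.3f +/- %.4f)  [n = %d, %d subsamples of %d%%]\n",
    x$slope_mean, x$slope_sd, x$intercept_mean, x$intercept_sd,
    x$n, x$n_boot, round(100 * x$frac)))
  invisible(x)
}

#' Tidy a bootstrapped scaling fit
#'
#' @param x a `scaling_fit`.
#' @param ... unused.
#' @return Tibble with one row per coefficient (`term`, `estimate`,
#'   `std.error`).
#' @export
tidy.scaling_fit <- function(x, ...) {
  tibble(term = c("slope", "intercept"),
         estimate = c(x$slope_mean, x$intercept_mean),
         std.error = c(x$slope_sd, x$intercept_sd))
}

#' One-row summary of a bootstrapped scaling fit
#'
#' @param x a `scaling_fit`.
#' @param ... unused.
#' @return One-row tibble.
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble(slope = x$slope_mean, slope_sd = x$slope_sd,
         intercept = x$intercept_mean, intercept_sd = x$intercept_sd,
         n = x$n, n_boot = x$n_boot, frac = x$frac)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Spearman rank correlation with large-sample p-value
#'
#' @param x,y numeric vectors (ties midranked).
#' @return List with `rho` and `p`; `rho = NA` with a warning when an input
#'   is constant.
#' @export
rank_correlation <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant input: correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Partial Spearman correlation given covariates
#'
#' Rank-transforms all variables, residualizes `x` and `y` on the covariates
#' (plus intercept) by least squares, and correlates the residuals; the
#' p-value uses the t approximation with `n - 2 - k` degrees of freedom.
#' Character or factor covariates are one-hot encoded. With no covariates
#' this reduces to [rank_correlation()].
#'
#' @param x,y numeric vectors.
#' @param covariates data frame (or vector/matrix) of covariates aligned
#'   with `x` and `y`; `NULL` for none.
#' @return List with `rho` and `p`.
#' @export
partial_rank_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates) ||
      (is.data.frame(covariates) && ncol(covariates) == 0)) {
    return(rank_correlation(x, y))
  }
  cv <- as.data.frame(covariates)
  if (nrow(cv) != length(x)) abort("covariates not aligned with x and y")
  ok <- complete.cases(x, y, cv)
  x <- x[ok]; y <- y[ok]; cv <- cv[ok, , drop = FALSE]
  n <- length(x)
  if (n < 5) abort("need at least 5 complete observations")
  cv_ranked <- as.data.frame(lapply(cv, function(col) {
    if (is.numeric(col)) rank(col) else factor(col)
  }))
  z <- stats::model.matrix(~ ., cv_ranked)
  if (qr(z)$rank < ncol(z)) abort("collinear covariates")
  if (ncol(z) >= n - 2) abort("collinear covariates leave no residual df")
  rx <- rank(x); ry <- rank(y)
  res_x <- stats::lsfit(z, rx, intercept = FALSE)$residuals
  res_y <- stats::lsfit(z, ry, intercept = FALSE)$residuals
  # a variable fully explained by the covariates has nothing left to couple
  null_tol <- 1e-8 * n
  if (sd(res_x) <= null_tol || sd(res_y) <= null_tol) {
    return(list(rho = 0, p = 1))
  }
  rho <- cor(res_x, res_y)
  df <- n - 2 - (ncol(z) - 1)
  if (df < 1) abort("not enough residual degrees of freedom")
  tstat <- rho * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), df))
}

#' Fisher z-transform of a correlation coefficient
#'
#' Variance-stabilizing atanh transform applied to per-animal couplings
#' before correlating them with volume across animals. The magnitude is
#' clipped just below 1 so that degenerate perfect correlations on toy
#' inputs stay finite; downstream rank statistics are unaffected by this
#' monotone transform.
#'
#' @param rho correlation value(s) in \[-1, 1\].
#' @return atanh(rho), clipped at |rho| <= 1 - 1e-12.
#' @export
fisher_z <- function(rho) {
  atanh(pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12))
}
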