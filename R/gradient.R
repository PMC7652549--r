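#' Fit the corticomedullary gradient from a layer profile
#'
#' Unweighted OLS of per-layer mean concentration (mmol/L) on per-layer
#' mean depth (mm). The signed slope is the corticomedullary gradient in
#' mmol/L/mm; positive means concentration rises with depth, i.e. towards
#' the medulla. A voxel-count-weighted fit is available via `weighted`.
#'
#' @param profile a [layer_profile()] (columns `depth_mm`, `mean`, and
#'   `n_voxels` if weighting), >= 3 layers.
#' @param weighted weight layers by voxel count.
#' @return A list of class `gradient_result`: `slope` (mmol/L/mm),
#'   `intercept` (mmol/L), `r_squared` in [0, 1] (0 for a flat profile),
#'   `p_value`, `n_layers`.
#' @export
fit_gradient <- function(profile, weighted = FALSE) {
  if (nrow(profile) < 3L) stop_data("gradient fit needs at least 3 layers")
  if (is.unsorted(profile$depth_mm, strictly = TRUE))
    stop_data("layer depths must be strictly increasing")
  if (weighted) {
    fit <- lm(mean ~ depth_mm, data = profile, weights = profile$n_voxels)
    cf <- coef(fit)
    res <- stats::residuals(fit)
    w <- profile$n_voxels
    sst <- sum(w * (profile$mean - stats::weighted.mean(profile$mean, w))^2)
    r2 <- if (sst == 0) 0 else 1 - sum(w * res^2) / sst
    out <- list(slope = cf[[2]], intercept = cf[[1]], r_squared = r2,
                p_value = NA_real_, n_layers = nrow(profile))
  } else {
    f <- linear_fit_r2(profile$depth_mm, profile$mean)
    out <- list(slope = f$slope, intercept = f$intercept,
                r_squared = f$r_squared, p_value = f$p_value,
                n_layers = nrow(profile))
  }
  structure(out, class = "gradient_result")
}

#' @export
print.gradient_result <- function(x, ...) {
  cat(sprintf(
    "<gradient_result> slope %.3f mmol/L/mm, intercept %.1f, R2 = %.4f (%d layers)\n",
    x$slope, x$intercept, x$r_squared, x$n_layers))
  invisible(x)
}

#' Gradient time course across a dynamic study
#'
#' Fits a corticomedullary gradient per subject and time point, then
#' compares each post-baseline time against baseline with a paired
#' two-sided Wilcoxon signed-rank test across subjects, Bonferroni-
#' corrected over the post-baseline family. The first significant time is
#' the smallest t with adjusted p < alpha; with few subjects and exact
#' tests the corrected p may be bounded above the attainable level, in
#' which case it is `NA`.
#'
#' @param profiles_by_time list over time points; each element a list over
#'   subjects of [layer_profile()]s (subject order consistent across
#'   times). The first time point is the baseline, t = 0.
#' @param times acquisition times, min; `times[1]` must be 0.
#' @param alpha significance level after correction.
#' @return A list of class `dynamic_gradient_series`: `table` (data.frame
#'   with per-time mean/sd slope, raw and adjusted p), `slopes` (subject x
#'   time matrix), `first_significant_time`, `alpha`.
#' @export
dynamic_gradient_series <- function(profiles_by_time, times, alpha = 0.05) {
  if (length(profiles_by_time) != length(times))
    stop_data("one profile set per time point is required")
  if (length(times) < 1L || times[1] != 0)
    stop_data("a baseline time point at t = 0 is required")
  n_sub <- length(profiles_by_time[[1]])
  slopes <- vapply(profiles_by_time, function(pl) {
    if (length(pl) != n_sub)
      stop_data("subject count must be constant across time points")
    vapply(pl, function(p) fit_gradient(p)$slope, numeric(1))
  }, numeric(n_sub))
  slopes <- matrix(slopes, nrow = n_sub)
  nt <- length(times)
  p_raw <- rep(NA_real_, nt)
  if (nt > 1L && n_sub >= 3L) {
    for (j in 2:nt)
      p_raw[j] <- wilcoxon_signed_rank(slopes[, j], slopes[, 1])$p_value
  }
  m <- nt - 1L
  p_adj <- c(NA_real_, bonferroni_adjust(p_raw[-1], m = max(m, 1L)))
  tab <- data.frame(time = times,
                    slope_mean = colMeans(slopes),
                    slope_sd = apply(slopes, 2, sd),
                    p_raw = p_raw, p_adj = p_adj,
                    significant = !is.na(p_adj) & p_adj < alpha)
  fst <- tab$time[which(tab$significant)[1]]
  structure(list(table = tab, slopes = slopes,
                 first_significant_time = if (length(fst)) fst else NA_real_,
                 alpha = alpha),
            class = "dynamic_gradient_series")
}

#' @export
print.dynamic_gradient_series <- function(x, ...) {
  cat("<dynamic_gradient_series>\n")
  print(transform(x$table, slope_mean = round(slope_mean, 3),
                  slope_sd = round(slope_sd, 3)))
  cat("first significant time:", x$first_significant_time, "min\n")
  invisible(x)
}
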