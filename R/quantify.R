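#' Fit the phantom signal-to-concentration calibration
#'
#' Ordinary least-squares line `signal = slope * conc + intercept` through
#' the phantom ROI mean signals. The intercept is fitted by default to
#' absorb the Rician noise floor; `force_zero_intercept = TRUE` constrains
#' the line through the origin. Per-compartment saturation factors
#' (dimensionless, from [saturation_factor()]) travel with the model so
#' that [apply_calibration()] can correct the bulk tissue-vs-phantom
#' T1-saturation difference.
#'
#' @param phantom_signals mean signal per phantom ROI.
#' @param phantom_concs corresponding concentrations, mmol/L; at least two
#'   distinct values.
#' @param f_tissue,f_phantom steady-state saturation factors of tissue and
#'   phantom compartments, in (0, 1].
#' @param force_zero_intercept fit through the origin.
#' @return A list of class `calibration_model`: `slope` (signal units per
#'   mmol/L), `intercept`, `residuals`, `f_tissue`, `f_phantom`.
#' @examples
#' fit_calibration(c(52, 98, 155), c(50, 100, 154))
#' @export
fit_calibration <- function(phantom_signals, phantom_concs,
                            f_tissue = 1, f_phantom = 1,
                            force_zero_intercept = FALSE) {
  if (length(phantom_signals) != length(phantom_concs))
    stop_data("signals and concentrations must have equal length")
  if (length(unique(phantom_concs)) < 2L)
    stop_data("calibration needs at least 2 distinct phantom concentrations")
  stopifnot(f_tissue > 0, f_tissue <= 1, f_phantom > 0, f_phantom <= 1)
  if (force_zero_intercept) {
    fit <- lm(phantom_signals ~ phantom_concs + 0)
    slope <- unname(coef(fit)[1]); intercept <- 0
  } else {
    fit <- lm(phantom_signals ~ phantom_concs)
    slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  }
  if (!is.finite(slope) || slope <= 0)
    stop_data("implausible calibration: fitted slope is not positive")
  structure(list(slope = slope, intercept = intercept,
                 residuals = unname(stats::residuals(fit)),
                 f_tissue = f_tissue, f_phantom = f_phantom),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> slope %.5g /mmol/L, intercept %.5g | f_t/f_ph %.4f\n",
    x$slope, x$intercept, x$f_tissue / x$f_phantom))
  cat(sprintf("  max |residual| %.3g\n",
              if (length(x$residuals)) max(abs(x$residuals)) else 0))
  invisible(x)
}

#' Transmit-B1 mapping by the double-angle method
#'
#' From two acquisitions at nominal flip angles alpha and 2*alpha, the
#' actual per-voxel flip is `acos(S_2a / (2 S_a))` (ratio clipped to
#' [-1, 1]); the B1 scale is actual/nominal flip. Voxels with `S_a = 0`
#' are undefined and returned as NA.
#'
#' @param vol_alpha,vol_2alpha magnitude volumes on the same grid.
#' @param nominal_alpha nominal flip angle, degrees, in (0, 90).
#' @return An [na_volume] of relative transmit scale (dimensionless).
#' @export
b1_map_double_angle <- function(vol_alpha, vol_2alpha, nominal_alpha) {
  if (!all(dim(vol_alpha) == dim(vol_2alpha)))
    stop_data("volumes must share a grid")
  if (nominal_alpha <= 0 || nominal_alpha >= 90)
    stop_data("nominal_alpha must be in (0, 90) degrees")
  s1 <- as_array(vol_alpha); s2 <- as_array(vol_2alpha)
  ratio <- s2 / (2 * s1)
  ratio[s1 == 0] <- NA_real_
  ratio <- pmin(pmax(ratio, -1), 1)
  actual <- acos(ratio) * 180 / pi
  na_volume(actual / nominal_alpha, voxel_spacing(vol_alpha), "b1-scale")
}

#' Apply a calibration model to a signal volume
#'
#' `conc = (signal - intercept) / (slope * b1_scale * f_tissue / f_phantom)`.
#' Negative calibrated concentrations are clipped to 0 (physical
#' constraint); the clipped-voxel count is attached as attribute
#' `n_clipped`. No receive-B1 correction is applied.
#'
#' @param signal an [na_volume] (or 3-D array) of magnitude signal.
#' @param model a [fit_calibration()] result.
#' @param b1 optional transmit-scale grid (e.g. [b1_map_double_angle()] or
#'   the generator's true field); `NULL` means uniform 1.
#' @param tissue_mask optional logical array; B1 validity is enforced
#'   inside it (`b1 <= 0` there is an error).
#' @return An [na_volume] of class concentration, mmol/L.
#' @export
apply_calibration <- function(signal, model, b1 = NULL, tissue_mask = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  sig <- as_array(signal)
  if (is.null(b1)) b1 <- array(1, dim(sig))
  b1 <- as_array(b1)
  if (!all(dim(b1) == dim(sig))) stop_data("B1 map must share the signal grid")
  if (!is.null(tissue_mask) && any(b1[as.logical(tissue_mask)] <= 0,
                                   na.rm = TRUE))
    stop_data("non-positive B1 scale inside the tissue mask")
  denom <- model$slope * b1 * (model$f_tissue / model$f_phantom)
  conc <- (sig - model$intercept) / denom
  n_clipped <- sum(conc < 0, na.rm = TRUE)
  conc[!is.na(conc) & conc < 0] <- 0
  sp <- attr(signal, "spacing")
  out <- na_volume(conc, if (is.null(sp)) c(1, 1, 1) else sp, "concentration")
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Regional summary of a concentration map
#'
#' Arithmetic mean and sample SD over in-mask voxels.
#'
#' @param conc concentration map (array or [na_volume]), mmol/L.
#' @param mask logical array, nonempty.
#' @param region region name for the summary row.
#' @return A one-row data.frame: `region`, `mean`, `sd`, `n_voxels`.
#' @export
region_mean <- function(conc, mask, region = "region") {
  mask <- as.logical(mask)
  if (!any(mask)) stop_data("empty mask for region '", region, "'")
  v <- as_array(conc)[mask]
  data.frame(region = region, mean = mean(v),
             sd = if (length(v) > 1) sd(v) else 0,
             n_voxels = length(v), stringsAsFactors = FALSE)
}

#' Quantify a synthetic subject end to end
#'
#' Convenience wrapper used by the study pipelines: measures the phantom
#' ROI mean signals (divided voxelwise by the transmit field, which is
#' known for synthetic data), fits the calibration line, computes the
#' tissue and phantom saturation factors from the configured T1/TR/flip,
#' and applies the calibration to the whole signal volume.
#'
#' @param subject a `synthetic_subject`.
#' @param force_zero_intercept see [fit_calibration()].
#' @return A list: `conc` ([na_volume], mmol/L), `model`
#'   (`calibration_model`), `regions` (data.frame of cortex, medulla and
#'   whole-kidney summaries).
#' @export
quantify_subject <- function(subject, force_zero_intercept = FALSE) {
  stopifnot(inherits(subject, "synthetic_subject"))
  cfg <- subject$config
  sig <- as_array(subject$signal)
  corrected <- sig / subject$b1
  ph_means <- vapply(phantom_masks(subject),
                     function(m) mean(corrected[m]), numeric(1))
  model <- fit_calibration(
    ph_means, cfg$phantom_concs,
    f_tissue = saturation_factor(cfg$t1_tissue, cfg$tr, cfg$flip_deg),
    f_phantom = saturation_factor(cfg$t1_phantom, cfg$tr, cfg$flip_deg),
    force_zero_intercept = force_zero_intercept)
  conc <- apply_calibration(subject$signal, model, b1 = subject$b1,
                            tissue_mask = kidney_mask(subject))
  regions <- rbind(
    region_mean(conc, cortex_mask(subject), "cortex"),
    region_mean(conc, medulla_mask(subject), "medulla"),
    region_mean(conc, kidney_mask(subject), "whole_kidney"))
  list(conc = conc, model = model, regions = regions)
}
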