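#' Synthetic subject configuration
#'
#' Describes one synthetic sodium-MRI subject: a two-compartment kidney
#' (outer ellipsoid = whole kidney, inner ellipsoid = medulla) plus agar
#' calibration phantoms in the field of view, the truth concentrations, the
#' acquisition model (T1 saturation, transmit-B1 inhomogeneity, Rician
#' noise) and the calibration ground truth.
#'
#' The truth concentration inside the kidney is either a `"step"` profile
#' (cortex voxels at `cortex_conc`, medulla voxels at `medulla_conc`) or the
#' default `"linear"` profile: an affine function of depth-from-surface
#' (mm). The linear ramp is anchored so that the cortex-mask mean equals
#' `cortex_conc`; its slope is `(medulla_conc - cortex_conc) /
#' cortex_medulla_depth_span`. When `cortex_medulla_depth_span` is `NULL`
#' (default) the span is the geometric separation between the compartment
#' mean depths, which also anchors the medulla-mask mean exactly at
#' `medulla_conc`.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing numeric length-3, mm per voxel, all > 0.
#' @param kidney_semiaxes outer ellipsoid semi-axes, mm.
#' @param medulla_semiaxes inner (medullary core) semi-axes, mm; must be
#'   strictly inside the outer ellipsoid. Default scales the outer axes to a
#'   0.33 medullary volume fraction.
#' @param kidney_center ellipsoid centre in mm (default: auto-placed right
#'   of the phantom column).
#' @param cortex_conc,medulla_conc compartment sodium concentrations,
#'   mmol/L.
#' @param profile_kind `"linear"` (default) or `"step"`.
#' @param cortex_medulla_depth_span mm; `NULL` for the geometric span.
#' @param phantom_concs calibration phantom concentrations, mmol/L;
#'   strictly positive and distinct. The highest default is the 154 mmol/L
#'   saline reference standard.
#' @param phantom_radius phantom sphere radius, mm.
#' @param phantom_centers optional matrix (one row per phantom) of centres
#'   in mm; auto-placed along the low-x edge when `NULL`.
#' @param t1_tissue,t1_phantom longitudinal relaxation times, ms.
#' @param tr repetition time, ms.
#' @param flip_deg excitation flip angle, degrees.
#' @param calib_slope_true true calibration slope, signal units per mmol/L.
#' @param b1_amp amplitude of the smooth multiplicative transmit-field
#'   deviation from 1 (0.10 = +/-10 percent).
#' @param noise_sigma Rician noise scale, signal units.
#' @param intersubject_cov relative SD of per-subject regional
#'   concentrations used by [generate_cohort()]; in [0, 1).
#' @param seed default RNG seed used when [generate_subject()] is called
#'   without one.
#' @return A validated list of class `subject_config`.
#' @seealso [human_subject_config()], [porcine_subject_config()],
#'   [generate_subject()]
#' @export
subject_config <- function(grid_shape = c(48L, 48L, 48L),
                           spacing = c(2, 2, 2),
                           kidney_semiaxes = c(30, 18, 18),
                           medulla_semiaxes = NULL,
                           kidney_center = NULL,
                           cortex_conc = 72,
                           medulla_conc = 136,
                           profile_kind = c("linear", "step"),
                           cortex_medulla_depth_span = NULL,
                           phantom_concs = c(50, 100, 154),
                           phantom_radius = 7,
                           phantom_centers = NULL,
                           t1_tissue = 26,
                           t1_phantom = 22,
                           tr = 30,
                           flip_deg = 45,
                           calib_slope_true = 1,
                           b1_amp = 0.10,
                           noise_sigma = 3,
                           intersubject_cov = 0.05,
                           seed = NULL) {
  profile_kind <- match.arg(profile_kind)
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    stop_data("grid_shape must be 3 axis lengths of at least 4 voxels")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_data("spacing must be positive on all axes")
  fov <- grid_shape * spacing
  if (is.null(medulla_semiaxes))
    medulla_semiaxes <- kidney_semiaxes * 0.33^(1 / 3)
  if (length(kidney_semiaxes) != 3L || any(kidney_semiaxes <= 0))
    stop_data("kidney_semiaxes must be 3 positive lengths in mm")
  if (length(medulla_semiaxes) != 3L || any(medulla_semiaxes <= 0))
    stop_data("medulla_semiaxes must be 3 positive lengths in mm")
  if (any(medulla_semiaxes >= kidney_semiaxes))
    stop_data("medullary core must lie strictly inside the outer ellipsoid")
  if (any(phantom_concs <= 0) || anyDuplicated(phantom_concs))
    stop_data("phantom_concs must be strictly positive and distinct")
  if (!is.null(cortex_medulla_depth_span) && cortex_medulla_depth_span <= 0)
    stop_data("cortex_medulla_depth_span must be positive")
  if (noise_sigma < 0) stop_data("noise_sigma must be >= 0")
  check_prob_fraction(intersubject_cov, "intersubject_cov")
  stopifnot(t1_tissue > 0, t1_phantom > 0, tr > 0,
            flip_deg > 0, flip_deg <= 90, calib_slope_true > 0, b1_amp >= 0)

  n_ph <- length(phantom_concs)
  if (is.null(phantom_centers)) {
    x0 <- phantom_radius + 0.08 * fov[1]
    ys <- seq(phantom_radius + 4, fov[2] - phantom_radius - 4,
              length.out = max(n_ph, 2L))[seq_len(n_ph)]
    phantom_centers <- cbind(rep(x0, n_ph), ys, rep(fov[3] / 2, n_ph))
  }
  phantom_centers <- matrix(as.numeric(phantom_centers), ncol = 3L)
  if (nrow(phantom_centers) != n_ph)
    stop_data("need one phantom centre per phantom concentration")
  if (is.null(kidney_center)) {
    # kidney right-aligned with a voxel of margin, centred in y and z;
    # build_labels() verifies it stays clear of the phantom column
    kidney_center <- c(fov[1] - kidney_semiaxes[1] - 2 * spacing[1],
                       fov[2] / 2, fov[3] / 2)
  }
  kidney_center <- as.numeric(kidney_center)

  # fit checks (one voxel of background margin), naming the overflowing axis
  ax <- c("x", "y", "z")
  lo <- kidney_center - kidney_semiaxes
  hi <- kidney_center + kidney_semiaxes
  bad <- which(lo < spacing | hi > fov - spacing)
  if (length(bad))
    stop_data("kidney ellipsoid overflows the grid along axis ", ax[bad[1]])
  for (k in seq_len(n_ph)) {
    blo <- phantom_centers[k, ] - phantom_radius
    bhi <- phantom_centers[k, ] + phantom_radius
    bad <- which(blo < 0 | bhi > fov)
    if (length(bad))
      stop_data("phantom ", k, " overflows the grid along axis ", ax[bad[1]])
  }

  structure(list(
    grid_shape = grid_shape, spacing = spacing,
    kidney_semiaxes = as.numeric(kidney_semiaxes),
    medulla_semiaxes = as.numeric(medulla_semiaxes),
    kidney_center = kidney_center,
    cortex_conc = cortex_conc, medulla_conc = medulla_conc,
    profile_kind = profile_kind,
    cortex_medulla_depth_span = cortex_medulla_depth_span,
    phantom_concs = as.numeric(phantom_concs),
    phantom_radius = phantom_radius, phantom_centers = phantom_centers,
    t1_tissue = t1_tissue, t1_phantom = t1_phantom,
    tr = tr, flip_deg = flip_deg, calib_slope_true = calib_slope_true,
    b1_amp = b1_amp, noise_sigma = noise_sigma,
    intersubject_cov = intersubject_cov, seed = seed
  ), class = "subject_config")
}

#' Preset configurations for the two study anatomies
#'
#' `human_subject_config()` is the volunteer default: 12-layer-scale kidney,
#' cortex 72 / medulla 136 mmol/L, medullary volume fraction 0.33.
#' `porcine_subject_config()` is the diuresis-study default: cortex 53 /
#' medulla 92 mmol/L, with the geometry scaled so the cortex-to-medulla mean
#' depth separation is near 14 mm, putting the default linear ramp's slope
#' near 2.8 mmol/L/mm.
#'
#' @param ... overrides passed on to [subject_config()].
#' @return A `subject_config`.
#' @export
human_subject_config <- function(...) {
  args <- list(...)
  defaults <- list(grid_shape = c(48L, 48L, 48L), spacing = c(2, 2, 2),
                   kidney_semiaxes = c(30, 18, 18),
                   cortex_conc = 72, medulla_conc = 136)
  do.call(subject_config, utils::modifyList(defaults, args))
}

#' @rdname human_subject_config
#' @export
porcine_subject_config <- function(...) {
  args <- list(...)
  defaults <- list(grid_shape = c(72L, 56L, 56L), spacing = c(2, 2, 2),
                   kidney_semiaxes = c(50, 31.7, 31.7),
                   medulla_semiaxes = c(50, 31.7, 31.7) * 0.48,
                   cortex_conc = 53, medulla_conc = 92)
  do.call(subject_config, utils::modifyList(defaults, args))
}

#' Furosemide washout model configuration
#'
#' The medullary truth concentration after a diuretic bolus at t = 0 follows
#' an exponential washout towards a plateau,
#' `m(t) = baseline - (baseline - plateau) * (1 - exp(-t / tau))`,
#' while the cortex drifts linearly. Defaults emulate a medullary fall from
#' 92 towards 69 mmol/L over 30 min with a small (non-significant) cortical
#' rise. On top of the deterministic curves, every scan's regional
#' concentrations fluctuate independently by `scan_cv` (within-animal
#' repeat-scan variability: physiology plus repositioning), which is what
#' keeps small drifts from being artificially sign-consistent across
#' animals.
#'
#' @param baseline_medulla,plateau_medulla mmol/L.
#' @param tau washout time constant, min.
#' @param cortex_drift cortical drift, mmol/L per 30 min.
#' @param scan_cv fractional SD of per-scan regional fluctuations, in
#'   [0, 1).
#' @param times acquisition times in min, sorted ascending, starting at 0.
#' @return A list of class `washout_config`.
#' @export
washout_config <- function(baseline_medulla = 92, plateau_medulla = 69,
                           tau = 10, cortex_drift = 2, scan_cv = 0.07,
                           times = seq(0, 30, by = 5)) {
  if (tau <= 0) stop_data("tau must be positive")
  if (length(times) < 1L || times[1] != 0 || is.unsorted(times, strictly = TRUE))
    stop_data("times must be strictly ascending and start at 0")
  if (baseline_medulla <= 0 || plateau_medulla <= 0)
    stop_data("medullary concentrations must be positive")
  check_prob_fraction(scan_cv, "scan_cv")
  structure(list(baseline_medulla = baseline_medulla,
                 plateau_medulla = plateau_medulla, tau = tau,
                 cortex_drift = cortex_drift, scan_cv = scan_cv,
                 times = as.numeric(times)),
            class = "washout_config")
}

#' Medullary washout curve
#'
#' @param washout a [washout_config()].
#' @param t times in min.
#' @return Medullary truth concentration (mmol/L) at each `t`.
#' @export
washout_medulla <- function(washout, t) {
  with(washout,
       baseline_medulla - (baseline_medulla - plateau_medulla) *
         (1 - exp(-t / tau)))
}

#' @export
print.subject_config <- function(x, ...) {
  cat(sprintf(
    "<subject_config> grid %s @ %s mm | cortex %g / medulla %g mmol/L (%s)\n",
    paste(x$grid_shape, collapse = "x"),
    paste(format(x$spacing), collapse = "x"),
    x$cortex_conc, x$medulla_conc, x$profile_kind))
  cat(sprintf("  phantoms: %s mmol/L | T1 %g/%g ms, TR %g ms, flip %g deg\n",
              paste(x$phantom_concs, collapse = ", "),
              x$t1_tissue, x$t1_phantom, x$tr, x$flip_deg))
  cat(sprintf("  noise sigma %g, B1 amp %g, inter-subject CoV %g\n",
              x$noise_sigma, x$b1_amp, x$intersubject_cov))
  invisible(x)
}
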