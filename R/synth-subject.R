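# Geometry helpers -----------------------------------------------------------

# voxel-centre coordinate grids in mm, as three arrays
coord_grids <- function(grid_shape, spacing) {
  xs <- (seq_len(grid_shape[1]) - 0.5) * spacing[1]
  ys <- (seq_len(grid_shape[2]) - 0.5) * spacing[2]
  zs <- (seq_len(grid_shape[3]) - 0.5) * spacing[3]
  list(x = array(rep(xs, times = grid_shape[2] * grid_shape[3]), grid_shape),
       y = array(rep(rep(ys, each = grid_shape[1]), times = grid_shape[3]),
                 grid_shape),
       z = array(rep(zs, each = grid_shape[1] * grid_shape[2]), grid_shape))
}

ellipsoid_mask <- function(coords, center, semiaxes) {
  ((coords$x - center[1]) / semiaxes[1])^2 +
    ((coords$y - center[2]) / semiaxes[2])^2 +
    ((coords$z - center[3]) / semiaxes[3])^2 <= 1
}

sphere_mask <- function(coords, center, radius) {
  (coords$x - center[1])^2 + (coords$y - center[2])^2 +
    (coords$z - center[3])^2 <= radius^2
}

# Label codes used throughout: 0 background, 1 cortex, 2 medulla, 10+k phantom k
LABEL_CORTEX <- 1L
LABEL_MEDULLA <- 2L
LABEL_PHANTOM_BASE <- 10L

build_labels <- function(config) {
  coords <- coord_grids(config$grid_shape, config$spacing)
  kidney <- ellipsoid_mask(coords, config$kidney_center, config$kidney_semiaxes)
  medulla <- ellipsoid_mask(coords, config$kidney_center, config$medulla_semiaxes)
  if (!any(kidney)) stop_data("kidney mask is empty at this grid resolution")
  if (!any(medulla)) stop_data("medullary core is empty at this grid resolution")
  labels <- array(0L, config$grid_shape)
  labels[kidney] <- LABEL_CORTEX
  labels[medulla] <- LABEL_MEDULLA
  for (k in seq_along(config$phantom_concs)) {
    ph <- sphere_mask(coords, config$phantom_centers[k, ], config$phantom_radius)
    if (!any(ph)) stop_data("phantom ", k, " is empty at this grid resolution")
    if (any(labels[ph] != 0L))
      stop_data("phantom ", k, " overlaps the kidney or another phantom")
    labels[ph] <- LABEL_PHANTOM_BASE + k
  }
  labels
}

#' Distance to the mask boundary
#'
#' Exact Euclidean distance (mm) from every in-mask voxel centre to the
#' nearest background voxel centre, respecting anisotropic voxel spacing.
#' Background voxels get 0. Voxels outside the grid are not treated as
#' background, so a mask touching the volume edge is rejected.
#'
#' @param mask logical 3-D array (or any array coerced with `!= 0`).
#' @param spacing mm per axis.
#' @return Numeric array of distances in mm.
#' @export
boundary_distance <- function(mask, spacing = attr(mask, "spacing")) {
  if (is.null(spacing)) stop_data("`spacing` is required")
  dm <- dim(mask)
  if (length(dm) != 3L) stop_data("`mask` must be a 3-D array")
  m <- array(as.logical(mask != 0), dm)
  if (!any(m)) stop_data("`mask` is empty")
  if (all(m)) stop_data("`mask` has no background voxels")
  edge <- any(m[1, , ]) || any(m[dm[1], , ]) ||
    any(m[, 1, ]) || any(m[, dm[2], ]) ||
    any(m[, , 1]) || any(m[, , dm[3]])
  if (edge) stop_data("`mask` touches the volume edge; pad the grid")
  d <- edt_cpp(m, dm, as.numeric(spacing))
  array(d, dm)
}

# Mask accessors --------------------------------------------------------------

#' Region masks of a synthetic subject
#'
#' @param subject a `synthetic_subject` from [generate_subject()].
#' @return Logical array (`kidney_mask`, `cortex_mask`, `medulla_mask`) or a
#'   list of logical arrays, one per phantom (`phantom_masks`).
#' @export
kidney_mask <- function(subject) subject$labels == LABEL_CORTEX |
  subject$labels == LABEL_MEDULLA

#' @rdname kidney_mask
#' @export
cortex_mask <- function(subject) subject$labels == LABEL_CORTEX

#' @rdname kidney_mask
#' @export
medulla_mask <- function(subject) subject$labels == LABEL_MEDULLA

#' @rdname kidney_mask
#' @export
phantom_masks <- function(subject) {
  lapply(seq_along(subject$config$phantom_concs),
         function(k) subject$labels == LABEL_PHANTOM_BASE + k)
}

# Truth profile ---------------------------------------------------------------

truth_concentration <- function(config, labels, depth) {
  conc <- array(0, config$grid_shape)
  cortex <- labels == LABEL_CORTEX
  medulla <- labels == LABEL_MEDULLA
  kidney <- cortex | medulla
  if (config$profile_kind == "step") {
    conc[cortex] <- config$cortex_conc
    conc[medulla] <- config$medulla_conc
  } else {
    d_cort <- mean(depth[cortex])
    d_med <- mean(depth[medulla])
    span <- config$cortex_medulla_depth_span
    if (is.null(span)) span <- d_med - d_cort
    if (span <= 0) stop_data("non-positive cortex-to-medulla depth span")
    slope <- (config$medulla_conc - config$cortex_conc) / span
    conc[kidney] <- config$cortex_conc + slope * (depth[kidney] - d_cort)
    if (any(conc[kidney] < 0))
      stop_data("linear profile yields negative concentrations; ",
                "check the depth span")
  }
  for (k in seq_along(config$phantom_concs))
    conc[labels == LABEL_PHANTOM_BASE + k] <- config$phantom_concs[k]
  conc
}

#' Geometric cortex-to-medulla depth span
#'
#' Separation (mm) between the mean boundary-distance of the medullary mask
#' and that of the cortical mask for a configuration's geometry. This is
#' the span that converts the configured concentration difference into the
#' default linear ramp's slope.
#'
#' @param config a [subject_config()].
#' @return Span in mm.
#' @export
compartment_depth_span <- function(config) {
  labels <- build_labels(config)
  depth <- boundary_distance(labels == LABEL_CORTEX | labels == LABEL_MEDULLA,
                             config$spacing)
  mean(depth[labels == LABEL_MEDULLA]) - mean(depth[labels == LABEL_CORTEX])
}

# Acquisition model -----------------------------------------------------------

# smooth low-order polynomial multiplicative transmit field, amplitude +/- amp
make_b1_field <- function(config, seed) {
  if (config$b1_amp == 0) return(array(1, config$grid_shape))
  coords <- coord_grids(config$grid_shape, config$spacing)
  fov <- config$grid_shape * config$spacing
  u <- 2 * coords$x / fov[1] - 1
  v <- 2 * coords$y / fov[2] - 1
  w <- 2 * coords$z / fov[3] - 1
  cf <- with_seed(seed, rnorm(9))
  p <- cf[1] * u + cf[2] * v + cf[3] * w +
    cf[4] * u * v + cf[5] * u * w + cf[6] * v * w +
    cf[7] * (u^2 - 1 / 3) + cf[8] * (v^2 - 1 / 3) + cf[9] * (w^2 - 1 / 3)
  1 + config$b1_amp * p / max(abs(p))
}

# magnitude (Rician) noise: |signal + complex Gaussian of scale sigma|
add_rician_noise <- function(signal, sigma, seed) {
  if (sigma == 0) return(signal)
  n <- length(signal)
  with_seed(seed, {
    re <- signal + sigma * rnorm(n)
    im <- sigma * rnorm(n)
    array(sqrt(re^2 + im^2), dim(signal))
  })
}

#' Generate one synthetic sodium-MRI subject
#'
#' Builds the two-compartment kidney and calibration phantoms on the voxel
#' grid, evaluates the truth concentration map, and simulates the magnitude
#' signal as
#' `signal = calib_slope_true * truth * f_sat(compartment T1) * B1 + Rician
#' noise`, where `f_sat` is the spoiled steady-state saturation factor (see
#' [saturation_factor()]) of the voxel's compartment and B1 is a smooth
#' multiplicative transmit field. Fully deterministic for a fixed seed.
#'
#' @param config a [subject_config()].
#' @param seed integer seed; overrides `config$seed`.
#' @return A list of class `synthetic_subject` with elements `signal` and
#'   `truth_conc` ([na_volume]s), `labels` (integer grid: 0 background,
#'   1 cortex, 2 medulla, 10+k phantom k), `b1` (the true transmit field),
#'   `depth` (boundary distance in mm over the kidney), saturation factors
#'   `f_tissue`/`f_phantom`, and the `config` and `seed` used.
#' @examples
#' s <- generate_subject(human_subject_config(noise_sigma = 0, b1_amp = 0),
#'                       seed = 1)
#' region_mean(s$truth_conc, medulla_mask(s), "medulla")
#' @export
generate_subject <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "subject_config"))
  if (is.null(seed)) stop_data("a seed is required (argument or config$seed)")
  labels <- build_labels(config)
  kidney <- labels == LABEL_CORTEX | labels == LABEL_MEDULLA
  depth <- boundary_distance(kidney, config$spacing)
  truth <- truth_concentration(config, labels, depth)

  f_tissue <- saturation_factor(config$t1_tissue, config$tr, config$flip_deg)
  f_phantom <- saturation_factor(config$t1_phantom, config$tr, config$flip_deg)
  fmap <- array(1, config$grid_shape)
  fmap[kidney] <- f_tissue
  fmap[labels >= LABEL_PHANTOM_BASE] <- f_phantom

  b1 <- make_b1_field(config, substream_seed(seed, "b1"))
  clean <- config$calib_slope_true * truth * fmap * b1
  signal <- add_rician_noise(clean, config$noise_sigma,
                             substream_seed(seed, "noise"))

  structure(list(
    signal = na_volume(signal, config$spacing, "na-signal"),
    truth_conc = na_volume(truth, config$spacing, "concentration"),
    labels = labels, b1 = b1, depth = depth,
    f_tissue = f_tissue, f_phantom = f_phantom,
    config = config, seed = as.integer(seed)
  ), class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf(
    "<synthetic_subject> seed %d | kidney %d voxels (medulla %d) | %d phantoms\n",
    x$seed, sum(kidney_mask(x)), sum(medulla_mask(x)),
    length(x$config$phantom_concs)))
  invisible(x)
}

#' Write a synthetic subject to NIfTI with a YAML sidecar
#'
#' Writes `signal.nii.gz`, `truth_conc.nii.gz`, `labels.nii.gz` and
#' `b1.nii.gz` plus `config.yaml` (the full configuration and seed) into a
#' directory.
#'
#' @param subject a `synthetic_subject`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- subject$config$spacing
  write_volume(subject$signal, file.path(dir, "signal.nii.gz"))
  write_volume(subject$truth_conc, file.path(dir, "truth_conc.nii.gz"))
  write_volume(array(as.numeric(subject$labels), dim(subject$labels)),
               file.path(dir, "labels.nii.gz"), spacing = sp)
  write_volume(subject$b1, file.path(dir, "b1.nii.gz"), spacing = sp)
  cfg <- subject$config
  cfg$phantom_centers <- apply(cfg$phantom_centers, 1, as.numeric,
                               simplify = FALSE)
  yaml::write_yaml(c(unclass(cfg), list(generated_seed = subject$seed)),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
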