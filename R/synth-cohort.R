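#' Generate a multi-site cohort of synthetic subjects
#'
#' Draws `n_per_site` subjects from each site configuration. Inter-subject
#' variability is applied to the regional truth concentrations only (the
#' geometry is shared): each subject's cortex and medulla concentrations
#' are drawn independently as `mean * (1 + cov * z)`, `z ~ N(0, 1)`, with
#' `cov = intersubject_cov` from the site config. Each subject is
#' reproducible from `(site, index, seed)` alone.
#'
#' @param n_per_site subjects per site (>= 0).
#' @param site_configs list of [subject_config()], one per site.
#' @param seed root seed.
#' @return List of `synthetic_subject`s, each with `$site` (index) and
#'   `$site_name`, with attribute `sites`.
#' @export
generate_cohort <- function(n_per_site, site_configs, seed) {
  stopifnot(n_per_site >= 0, length(site_configs) >= 1)
  site_names <- names(site_configs)
  if (is.null(site_names)) site_names <- LETTERS[seq_along(site_configs)]
  out <- list()
  for (s in seq_along(site_configs)) {
    cfg <- site_configs[[s]]
    stopifnot(inherits(cfg, "subject_config"))
    for (i in seq_len(n_per_site)) {
      sub_seed <- substream_seed(seed, sprintf("site%d-subject%d", s, i))
      cov <- cfg$intersubject_cov
      z <- with_seed(substream_seed(sub_seed, "regional-conc"), rnorm(2))
      cfg_i <- cfg
      cfg_i$cortex_conc <- cfg$cortex_conc * (1 + cov * z[1])
      cfg_i$medulla_conc <- cfg$medulla_conc * (1 + cov * z[2])
      if (cfg_i$cortex_conc <= 0 || cfg_i$medulla_conc <= 0)
        stop_data("inter-subject draw produced a non-positive concentration")
      subj <- generate_subject(cfg_i, seed = sub_seed)
      subj$site <- s
      subj$site_name <- site_names[s]
      subj$index <- i
      out[[length(out) + 1L]] <- subj
    }
  }
  attr(out, "sites") <- site_names
  out
}

#' Generate a dynamic furosemide study for one subject
#'
#' One `synthetic_subject` per acquisition time, sharing anatomy and
#' transmit field. The medullary truth follows the exponential washout
#' `m(t) = baseline - (baseline - plateau) * (1 - exp(-t / tau))` and the
#' cortex drifts linearly (`cortex_drift` mmol/L per 30 min); on top of
#' these curves each scan's cortical and medullary concentrations
#' fluctuate independently by the washout's `scan_cv` (repeat-scan
#' variability), and Rician noise is drawn freshly at every time point.
#'
#' @param config a [subject_config()]; its `cortex_conc` is the cortical
#'   baseline, and the medullary baseline comes from `washout`.
#' @param washout a [washout_config()].
#' @param seed integer seed.
#' @return A list of class `dynamic_subject_series`: `times` (min),
#'   `subjects` (one per time), `washout`, `config`, `seed`.
#' @export
generate_dynamic_study <- function(config, washout, seed) {
  stopifnot(inherits(config, "subject_config"),
            inherits(washout, "washout_config"))
  times <- washout$times
  med <- washout_medulla(washout, times)
  cort <- config$cortex_conc + washout$cortex_drift * times / 30
  scan_cv <- washout$scan_cv %||% 0
  if (scan_cv > 0) {
    z <- with_seed(substream_seed(seed, "scan-fluctuation"),
                   matrix(rnorm(2 * length(times)), ncol = 2))
    cort <- cort * (1 + scan_cv * z[, 1])
    med <- med * (1 + scan_cv * z[, 2])
  }
  if (any(med <= 0) || any(cort <= 0))
    stop_data("washout model yields a non-positive concentration")
  # same anatomy and transmit field at every time point; fresh noise per time
  subjects <- lapply(seq_along(times), function(i) {
    cfg_t <- config
    cfg_t$medulla_conc <- med[i]
    cfg_t$cortex_conc <- cort[i]
    sigma <- cfg_t$noise_sigma
    cfg_t$noise_sigma <- 0
    s <- generate_subject(cfg_t, seed = seed)
    noisy <- add_rician_noise(as_array(s$signal), sigma,
                              substream_seed(seed, paste0("noise-t", i)))
    s$signal <- na_volume(noisy, cfg_t$spacing, "na-signal")
    s$config$noise_sigma <- sigma
    s$time <- times[i]
    s
  })
  structure(list(times = times, subjects = subjects, washout = washout,
                 config = config, seed = as.integer(seed)),
            class = "dynamic_subject_series")
}

#' Generate an inversion-recovery volume series
#'
#' Per-voxel magnitude `|S0 (1 - 2 exp(-TI / T1))|` plus Rician noise, with
#' `S0 = calib_slope_true * truth concentration` and T1 set by compartment
#' (tissue vs phantom).
#'
#' @param config a [subject_config()]; `noise_sigma` sets the noise scale.
#' @param tis inversion times in ms, at least 3, strictly increasing.
#' @param seed integer seed.
#' @return A list of class `ir_series`: `tis`, `volumes` (list of
#'   [na_volume]s), `labels`, `config`, `seed`.
#' @export
generate_ir_series <- function(config, tis = c(5, 10, 15, 20, 25, 30, 45, 70),
                               seed = config$seed) {
  stopifnot(inherits(config, "subject_config"))
  tis <- as.numeric(tis)
  if (length(tis) < 3L || any(tis <= 0) || is.unsorted(tis, strictly = TRUE))
    stop_data("need >= 3 strictly increasing positive inversion times (ms)")
  if (is.null(seed)) stop_data("a seed is required")
  labels <- build_labels(config)
  kidney <- labels == LABEL_CORTEX | labels == LABEL_MEDULLA
  depth <- boundary_distance(kidney, config$spacing)
  truth <- truth_concentration(config, labels, depth)
  s0 <- config$calib_slope_true * truth
  t1 <- array(NA_real_, config$grid_shape)
  t1[kidney] <- config$t1_tissue
  t1[labels >= LABEL_PHANTOM_BASE] <- config$t1_phantom
  volumes <- lapply(seq_along(tis), function(i) {
    clean <- array(0, config$grid_shape)
    inside <- !is.na(t1)
    clean[inside] <- s0[inside] * abs(1 - 2 * exp(-tis[i] / t1[inside]))
    noisy <- add_rician_noise(clean, config$noise_sigma,
                              substream_seed(seed, paste0("ir-ti", i)))
    na_volume(noisy, config$spacing, "ir-magnitude")
  })
  structure(list(tis = tis, volumes = volumes, labels = labels,
                 config = config, seed = as.integer(seed)),
            class = "ir_series")
}

#' Simulate a serum electrolyte panel
#'
#' Each analyte stays constant at its baseline with independent
#' multiplicative noise (`value = baseline * (1 + noise_cv * z)`), so serum
#' chemistry is flat by construction while imaging changes — the serum
#' stream is independent of the imaging streams. Defaults follow
#' physiological values (sodium 139, potassium 4.0, chloride 103 mmol/L);
#' note the source report prints the potassium and chloride labels
#' apparently transposed (103 vs 3.0), which is left as found in its text
#' and corrected only in these defaults.
#'
#' @param baseline named numeric vector of baseline concentrations, mmol/L.
#' @param noise_cv fractional coefficient of variation of the noise (>= 0).
#' @param times sampling times, min.
#' @param seed integer seed.
#' @return A data.frame of class `serum_panel`: `time` plus one column per
#'   analyte.
#' @export
simulate_serum <- function(baseline = c(sodium = 139, potassium = 4.0,
                                        chloride = 103),
                           noise_cv = 0.01, times = seq(0, 30, by = 5),
                           seed = 1L) {
  if (noise_cv < 0) stop_data("noise_cv must be >= 0")
  if (any(baseline <= 0)) stop_data("baseline concentrations must be positive")
  nm <- names(baseline)
  if (is.null(nm)) stop_data("`baseline` must be a named vector")
  out <- data.frame(time = as.numeric(times))
  for (a in nm) {
    z <- with_seed(substream_seed(seed, paste0("serum-", a)),
                   rnorm(length(times)))
    out[[a]] <- baseline[[a]] * (1 + noise_cv * z)
  }
  class(out) <- c("serum_panel", "data.frame")
  out
}

#' Maximum percentage change of a serum series versus baseline
#'
#' @param values analyte concentrations over time.
#' @param baseline reference value; defaults to the first element.
#' @return Largest `100 * |value - baseline| / baseline` over the series.
#' @export
serum_max_pct_change <- function(values, baseline = values[1]) {
  if (baseline == 0) stop_data("baseline must be nonzero")
  max(abs(values - baseline) / abs(baseline)) * 100
}
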