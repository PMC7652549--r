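test_that("identity acquisition chain reproduces the truth map exactly", {
  # unit slope, no noise, no B1 deviation, fully relaxed (TR >> T1, 90 deg)
  cfg <- small_human_config(noise_sigma = 0, b1_amp = 0,
                            calib_slope_true = 1, tr = 1e9, flip_deg = 90)
  s <- generate_subject(cfg, seed = 11)
  expect_equal(as_arr(s$signal), as_arr(s$truth_conc), tolerance = 1e-12)
  # phantoms carry their configured concentrations
  for (k in seq_along(cfg$phantom_concs))
    expect_equal(unique(s$truth_conc[s$labels == 10L + k]),
                 cfg$phantom_concs[k])
})

test_that("masks partition the anatomy", {
  s <- generate_subject(small_human_config(), seed = 2)
  expect_true(all(xor(cortex_mask(s), medulla_mask(s)) == kidney_mask(s)))
  expect_false(any(cortex_mask(s) & medulla_mask(s)))
  for (ph in phantom_masks(s)) {
    expect_gt(sum(ph), 0)
    expect_false(any(ph & kidney_mask(s)))
  }
})

test_that("human default truth regional means match the configured values", {
  s <- generate_subject(human_subject_config(noise_sigma = 0, b1_amp = 0),
                       seed = 1)
  expect_equal(mean(s$truth_conc[cortex_mask(s)]), 72, tolerance = 1e-10)
  expect_equal(mean(s$truth_conc[medulla_mask(s)]), 136, tolerance = 1e-10)
  # whole kidney is the volume-weighted mixture of the two compartments
  f <- sum(medulla_mask(s)) / sum(kidney_mask(s))
  expect_equal(mean(s$truth_conc[kidney_mask(s)]), f * 136 + (1 - f) * 72,
               tolerance = 1e-10)
  expect_equal(f, 0.33, tolerance = 0.02)
})

test_that("generation is bit-reproducible for a fixed seed", {
  cfg <- small_human_config()
  a <- generate_subject(cfg, seed = 42)
  b <- generate_subject(cfg, seed = 42)
  expect_identical(as_arr(a$signal), as_arr(b$signal))
  expect_identical(a$b1, b$b1)
  c <- generate_subject(cfg, seed = 43)
  expect_false(identical(as_arr(a$signal), as_arr(c$signal)))
})

test_that("magnitude noise is Rayleigh at zero signal and Gaussian at high SNR", {
  sigma <- 3
  s <- generate_subject(human_subject_config(noise_sigma = sigma), seed = 5)
  bg <- s$signal[s$labels == 0L]
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.02)
  # uniform high-SNR region (step profile keeps the medulla constant)
  s2 <- generate_subject(human_subject_config(noise_sigma = sigma, b1_amp = 0,
                                              profile_kind = "step"),
                         seed = 5)
  med <- s2$signal[medulla_mask(s2)]
  clean <- 136 * s2$config$calib_slope_true * s2$f_tissue
  expect_gt(clean / sigma, 10)
  expect_equal(mean(med), clean, tolerance = 0.01)
  expect_equal(sd(med), sigma, tolerance = 0.1)
})

test_that("linear profile is voxelwise affine in depth; step profile is two-valued", {
  s <- generate_subject(small_human_config(noise_sigma = 0, b1_amp = 0),
                       seed = 3)
  k <- kidney_mask(s)
  fit <- lm(conc ~ depth, data.frame(conc = s$truth_conc[k],
                                     depth = s$depth[k]))
  expect_lt(max(abs(residuals(fit))), 1e-8)
  s2 <- generate_subject(small_human_config(noise_sigma = 0, b1_amp = 0,
                                            profile_kind = "step"), seed = 3)
  expect_identical(sort(unique(s2$truth_conc[kidney_mask(s2)])), c(72, 136))
})

test_that("geometry that does not fit the grid is rejected naming the axis", {
  expect_error(subject_config(grid_shape = c(24L, 24L, 24L),
                              kidney_semiaxes = c(40, 10, 10)),
               "axis x")
  expect_error(subject_config(grid_shape = c(48L, 48L, 12L),
                              kidney_semiaxes = c(20, 10, 14),
                              kidney_center = c(60, 48, 12)),
               "axis z")
  expect_error(subject_config(phantom_centers = rbind(c(5, 5, 5)),
                              phantom_concs = 154, phantom_radius = 7),
               "phantom 1")
})

test_that("phantoms overlapping the kidney are rejected", {
  cfg <- small_human_config()
  cfg$phantom_centers[1, ] <- cfg$kidney_center
  expect_error(generate_subject(cfg, seed = 1), "overlaps")
})

test_that("cohort generation recovers site means and inter-subject CoV", {
  cfg <- small_human_config(medulla_conc = 137, intersubject_cov = 0.05)
  coh <- generate_cohort(50, list(A = cfg), seed = 9)
  med_truth <- vapply(coh, function(s) mean(s$truth_conc[medulla_mask(s)]),
                      numeric(1))
  expect_equal(mean(med_truth), 137, tolerance = 0.03)
  cv <- cov_percent(med_truth)
  expect_gt(cv, 3.2)
  expect_lt(cv, 7)
  # empty cohort and per-(site, index, seed) reproducibility
  expect_length(generate_cohort(0, list(A = cfg), seed = 9), 0)
  coh2 <- generate_cohort(2, list(A = cfg), seed = 9)
  expect_identical(as_arr(coh2[[2]]$signal), as_arr(coh[[2]]$signal))
})

test_that("two-site cohort separates configured site means", {
  ca <- small_human_config(medulla_conc = 137, intersubject_cov = 0.02)
  cb <- small_human_config(medulla_conc = 133, intersubject_cov = 0.02)
  coh <- generate_cohort(6, list(A = ca, B = cb), seed = 4)
  med <- vapply(coh, function(s) mean(s$truth_conc[medulla_mask(s)]),
                numeric(1))
  site <- vapply(coh, function(s) s$site_name, character(1))
  expect_equal(mean(med[site == "A"]), 137, tolerance = 0.03)
  expect_equal(mean(med[site == "B"]), 133, tolerance = 0.03)
})

test_that("washout model follows its closed form and degenerates cleanly", {
  w <- washout_config(baseline_medulla = 92, plateau_medulla = 69, tau = 10)
  expect_equal(washout_medulla(w, 0), 92)
  expect_equal(washout_medulla(w, 10), 92 - 23 * (1 - exp(-1)))
  expect_equal(washout_medulla(w, 30), 92 - 23 * (1 - exp(-3)),
               tolerance = 1e-12)
  # monotone nonincreasing when plateau < baseline
  expect_true(all(diff(washout_medulla(w, seq(0, 30, 1))) <= 0))
  expect_error(washout_config(tau = -1), "tau")
  expect_error(washout_config(times = c(5, 10)), "start at 0")
})

test_that("dynamic study truth medullary means follow the washout curve", {
  cfg <- small_porcine_config(noise_sigma = 0, b1_amp = 0)
  w <- washout_config(scan_cv = 0, cortex_drift = 0)
  dyn <- generate_dynamic_study(cfg, w, seed = 6)
  med <- vapply(dyn$subjects, function(s)
    mean(s$truth_conc[medulla_mask(s)]), numeric(1))
  expect_equal(med[1], 92, tolerance = 1e-10)
  expect_equal(med[length(med)], 92 - 23 * (1 - exp(-3)), tolerance = 1e-10)
  expect_true(all(diff(med) < 0))
  # same anatomy at every time point
  expect_identical(dyn$subjects[[1]]$labels, dyn$subjects[[4]]$labels)
  expect_identical(dyn$subjects[[1]]$b1, dyn$subjects[[4]]$b1)
})

test_that("zero-effect dynamic study is constant up to noise", {
  cfg <- small_porcine_config(noise_sigma = 0, b1_amp = 0)
  w <- washout_config(baseline_medulla = 92, plateau_medulla = 92,
                      cortex_drift = 0, scan_cv = 0)
  dyn <- generate_dynamic_study(cfg, w, seed = 6)
  expect_identical(as_arr(dyn$subjects[[1]]$truth_conc),
                   as_arr(dyn$subjects[[7]]$truth_conc))
})

test_that("dynamic study rejects curves that reach nonpositive concentrations", {
  cfg <- small_porcine_config(cortex_conc = 5)
  w <- washout_config(cortex_drift = -10, scan_cv = 0)
  expect_error(generate_dynamic_study(cfg, w, seed = 1), "non-positive")
})

test_that("IR series obeys the inversion-recovery signal equation", {
  cfg <- small_human_config(noise_sigma = 0, b1_amp = 0, profile_kind = "step")
  null_ti <- 26 * log(2)
  ir <- generate_ir_series(cfg, tis = c(5, null_ti, 2600), seed = 8)
  med <- medulla_mask(list(labels = ir$labels,
                           config = cfg))
  s0 <- 136 * cfg$calib_slope_true
  # TI >> T1: full recovery to S0
  expect_equal(mean(ir$volumes[[3]][med]), s0, tolerance = 1e-6)
  # noiseless null point at TI = T1 ln 2
  expect_lt(max(ir$volumes[[2]][med]), 1e-9 * s0)
  expect_error(generate_ir_series(cfg, tis = c(10, 20), seed = 1), ">= 3")
})

test_that("serum panels stay flat with independent multiplicative noise", {
  p <- simulate_serum(noise_cv = 0, seed = 3)
  expect_true(all(p$sodium == 139) && all(p$potassium == 4) &&
                all(p$chloride == 103))
  p2 <- simulate_serum(noise_cv = 0.01, times = seq(0, 30, 5), seed = 3)
  expect_equal(mean(p2$sodium), 139, tolerance = 0.02)
  expect_true(all(p2[c("sodium", "potassium", "chloride")] > 0))
  # hand-checked maximum percent change
  expect_equal(serum_max_pct_change(c(100, 99, 101), 100), 1)
  # serum stream independent of a same-seed imaging stream
  expect_identical(simulate_serum(seed = 3), p3 <- simulate_serum(seed = 3))
})

test_that("subjects round-trip through NIfTI with spacing preserved", {
  s <- generate_subject(small_human_config(), seed = 12)
  dir <- withr::local_tempdir()
  write_subject(s, dir)
  sig <- read_volume(file.path(dir, "signal.nii.gz"))
  expect_equal(as_arr(sig), as_arr(s$signal), tolerance = 1e-6)
  expect_equal(voxel_spacing(sig), s$config$spacing)
  lab <- read_volume(file.path(dir, "labels.nii.gz"))
  expect_identical(array(as.integer(lab), dim(lab)), s$labels)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg$medulla_conc, s$config$medulla_conc)
  expect_equal(cfg$generated_seed, s$seed)
})
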