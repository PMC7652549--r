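test_that("calibration fit matches the normal-equations oracle", {
  m <- fit_calibration(c(0, 100), c(0, 100))
  expect_equal(m$slope, 1)
  expect_equal(m$intercept, 0)

  sig <- c(52, 98, 155); conc <- c(50, 100, 154)
  m2 <- fit_calibration(sig, conc)
  # brute-force normal equations
  X <- cbind(1, conc)
  beta <- solve(t(X) %*% X, t(X) %*% sig)
  expect_equal(m2$intercept, beta[1], tolerance = 1e-12)
  expect_equal(m2$slope, beta[2], tolerance = 1e-12)
  expect_equal(m2$residuals, as.vector(sig - X %*% beta), tolerance = 1e-12)

  # the 154 mmol/L saline standard anchors the top of the line
  expect_equal(max(conc), 154)
  m3 <- fit_calibration(c(10, 100), c(10, 100), force_zero_intercept = TRUE)
  expect_equal(m3$intercept, 0)

  expect_error(fit_calibration(c(1, 2), c(100, 100)), "distinct")
  expect_error(fit_calibration(c(100, 1), c(10, 100)), "slope")
})

test_that("double-angle B1 mapping inverts its forward model", {
  dm <- c(6, 5, 4); sp <- c(2, 2, 2)
  scale_true <- array(seq(0.85, 1.1, length.out = prod(dm)), dm)
  nominal <- 60
  a <- scale_true * nominal * pi / 180
  s1 <- na_volume(sin(a), sp)
  s2 <- na_volume(sin(2 * a), sp)
  b1 <- b1_map_double_angle(s1, s2, nominal)
  expect_equal(as_arr(b1), scale_true, tolerance = 1e-10)

  # uniform nominal flip gives a flat unit map
  u <- na_volume(array(sin(nominal * pi / 180), dm), sp)
  u2 <- na_volume(array(sin(2 * nominal * pi / 180), dm), sp)
  expect_equal(unique(as.vector(b1_map_double_angle(u, u2, nominal))), 1,
               tolerance = 1e-12)

  # S_2a = 0 reads as a 90-degree actual flip; S_a = 0 is undefined
  z <- b1_map_double_angle(na_volume(array(c(0.5, 0), c(2, 1, 1)), sp[1:3]),
                           na_volume(array(0, c(2, 1, 1)), sp[1:3]), 45)
  expect_equal(z[1, 1, 1], 2)  # 90 / 45
  expect_true(is.na(z[2, 1, 1]))
})

test_that("apply_calibration follows its closed form and clips negatives", {
  dm <- c(4, 4, 4); sp <- c(2, 2, 2)
  sig <- na_volume(array(100, dm), sp)
  ident <- fit_calibration(c(0, 100), c(0, 100))
  expect_equal(as_arr(apply_calibration(sig, ident)), array(100, dm))

  m <- fit_calibration(c(0, 100), c(0, 100), f_tissue = 0.97, f_phantom = 1)
  conc <- apply_calibration(sig, m)
  expect_equal(conc[1, 1, 1], 100 / 0.97, tolerance = 1e-12) # 103.09 mmol/L

  neg <- na_volume(array(c(-5, rep(10, prod(dm) - 1)), dm), sp)
  out <- apply_calibration(neg, ident)
  expect_equal(attr(out, "n_clipped"), 1L)
  expect_equal(out[1, 1, 1], 0)

  bad_b1 <- array(1, dm); bad_b1[2, 2, 2] <- 0
  mask <- array(TRUE, dm)
  expect_error(apply_calibration(sig, ident, b1 = bad_b1, tissue_mask = mask),
               "B1")
})

test_that("region_mean computes mean/sd and is permutation- and scale-consistent", {
  dm <- c(3, 3, 3)
  v <- array(72, dm)
  r <- region_mean(v, array(TRUE, dm), "cortex")
  expect_equal(r$mean, 72)
  expect_equal(r$sd, 0)
  expect_equal(r$n_voxels, 27L)

  m <- array(FALSE, dm); m[1:3] <- TRUE
  v2 <- array(0, dm); v2[1:3] <- c(1, 2, 3)
  r2 <- region_mean(v2, m)
  expect_equal(r2$mean, 2)
  expect_equal(r2$sd, 1)

  # permutation invariance and linearity in the map
  set.seed(31)
  v3 <- array(rnorm(27), dm)
  perm <- sample(27)
  v3p <- array(0, dm); v3p[perm] <- as.vector(v3)
  mp <- array(FALSE, dm); mp[perm[1:10]] <- TRUE
  m0 <- array(FALSE, dm); m0[1:10] <- TRUE
  expect_equal(region_mean(v3p, mp)$mean, region_mean(v3, m0)$mean)
  expect_equal(region_mean(3 * v3, m0)$mean, 3 * region_mean(v3, m0)$mean)

  expect_error(region_mean(v, array(FALSE, dm), "x"), "empty mask")
})

test_that("noiseless round trip recovers the truth map below 1e-6 relative error", {
  s <- generate_subject(small_human_config(noise_sigma = 0), seed = 21)
  q <- quantify_subject(s)
  k <- kidney_mask(s)
  rel <- abs(q$conc[k] - s$truth_conc[k]) / s$truth_conc[k]
  expect_lt(max(rel), 1e-6)
})

test_that("B1 correction removes a known +/-10% multiplicative field", {
  s <- generate_subject(small_human_config(noise_sigma = 0, b1_amp = 0.10),
                        seed = 22)
  expect_equal(max(abs(s$b1 - 1)), 0.10)  # the field really deviates
  q <- quantify_subject(s)
  for (r in c("cortex", "medulla")) {
    got <- q$regions$mean[q$regions$region == r]
    want <- if (r == "cortex") 72 else 136
    expect_equal(got, want, tolerance = 0.001)
  }
})

test_that("saturation mismatch between tissue and phantom is corrected", {
  # without the f_tissue/f_phantom ratio the round trip would carry the
  # ~3% bulk saturation bias; with it the truth is recovered
  cfg <- small_human_config(noise_sigma = 0, b1_amp = 0, tr = 30,
                            flip_deg = 45)
  s <- generate_subject(cfg, seed = 23)
  q <- quantify_subject(s)
  expect_equal(q$regions$mean[q$regions$region == "medulla"], 136,
               tolerance = 1e-9)
  bias <- saturation_bias(cfg$t1_tissue, cfg$t1_phantom, cfg$tr, cfg$flip_deg)
  naive <- apply_calibration(s$signal, fit_calibration(
    vapply(phantom_masks(s), function(m) mean((s$signal / s$b1)[m]),
           numeric(1)),
    cfg$phantom_concs), b1 = s$b1)
  naive_med <- region_mean(naive, medulla_mask(s))$mean
  expect_equal(100 * abs(naive_med - 136) / 136, bias, tolerance = 0.01)
})
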