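# Independent oracles and small fixtures, built in code at test time.

# strip class/spacing attributes for raw array comparison
as_arr <- function(x) {
  a <- unclass(x)
  attributes(a) <- list(dim = dim(x))
  a
}

# Brute-force nearest-background distance (mm): the O(V^2) oracle for the
# separable distance transform.
bf_distance <- function(mask, spacing) {
  dm <- dim(mask)
  d <- array(0, dm)
  idx_in <- which(mask)
  idx_out <- which(!mask)
  ai <- arrayInd(idx_in, dm)
  ao <- arrayInd(idx_out, dm)
  for (i in seq_along(idx_in)) {
    dx <- (ao[, 1] - ai[i, 1]) * spacing[1]
    dy <- (ao[, 2] - ai[i, 2]) * spacing[2]
    dz <- (ao[, 3] - ai[i, 3]) * spacing[3]
    d[idx_in[i]] <- sqrt(min(dx * dx + dy * dy + dz * dz))
  }
  d
}

# Brute-force layer labels sharing the package's binning convention
# (equal-width bins over the occupied depth range, deepest ties inward).
bf_layers <- function(mask, n_layers, spacing) {
  d <- bf_distance(mask, spacing)
  dv <- d[mask]
  lo <- min(dv); hi <- max(dv)
  lab <- array(0L, dim(mask))
  if (hi == lo) {
    lab[mask] <- 1L
  } else {
    k <- floor((dv - lo) / (hi - lo) * n_layers) + 1L
    lab[mask] <- pmin(k, n_layers)
  }
  lab
}

# Recursive exhaustive two-sided signed-rank p-value (independent of the
# vectorised enumeration in the package).
bf_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  vals <- numeric(2^n)
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    vals[code + 1] <- sum(r[bits == 1L])
  }
  min(1, 2 * min(mean(vals <= v_obs + 1e-9), mean(vals >= v_obs - 1e-9)))
}

# Recursive exhaustive two-sided rank-sum p-value via explicit subset
# generation (not utils::combn, which the implementation uses).
bf_rank_sum_p <- function(a, b) {
  na <- length(a); n <- na + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(na)])
  subsets <- function(n, k, from = 1) {
    if (k == 0) return(list(integer(0)))
    if (from > n) return(list())
    c(lapply(subsets(n, k - 1, from + 1), function(s) c(from, s)),
      subsets(n, k, from + 1))
  }
  vals <- vapply(subsets(n, na), function(s) sum(r[s]), numeric(1))
  min(1, 2 * min(mean(vals <= w_obs + 1e-9), mean(vals >= w_obs - 1e-9)))
}

# Small, fast generator configs for tests that exercise structure rather
# than the full-size default study conditions.
small_human_config <- function(...) {
  human_subject_config(grid_shape = c(28L, 24L, 24L), spacing = c(2, 2, 2),
                       kidney_semiaxes = c(16, 10, 10), phantom_radius = 4,
                       ...)
}

small_porcine_config <- function(...) {
  porcine_subject_config(grid_shape = c(36L, 28L, 28L), spacing = c(2, 2, 2),
                         kidney_semiaxes = c(24, 15, 15),
                         medulla_semiaxes = c(24, 15, 15) * 0.48,
                         phantom_radius = 4, ...)
}

# digital sphere / ellipsoid / blob masks for the layer oracle
sphere_mask_fixture <- function(dm, center, radius_vox, spacing = c(1, 1, 1)) {
  g <- expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]), z = seq_len(dm[3]))
  inside <- ((g$x - center[1]) * spacing[1])^2 +
    ((g$y - center[2]) * spacing[2])^2 +
    ((g$z - center[3]) * spacing[3])^2 <= radius_vox^2
  array(inside, dm)
}

ellipsoid_mask_fixture <- function(dm, center, semi) {
  g <- expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]), z = seq_len(dm[3]))
  inside <- ((g$x - center[1]) / semi[1])^2 + ((g$y - center[2]) / semi[2])^2 +
    ((g$z - center[3]) / semi[3])^2 <= 1
  array(inside, dm)
}

blob_mask_fixture <- function(dm, seed) {
  set.seed(seed)
  m <- array(FALSE, dm)
  c0 <- dm / 2
  for (i in 1:4) {
    cc <- pmin(pmax(round(c0 + rnorm(3, sd = 2)), 5), dm - 4)
    m <- m | sphere_mask_fixture(dm, cc, runif(1, 2, 3.4))
  }
  m
}

# Cached default study runs shared across acceptance checks (the cohort
# and dynamic study are each generated once per test session).
.study_cache <- new.env(parent = emptyenv())

default_repro_report <- function() {
  if (is.null(.study_cache$repro))
    .study_cache$repro <- run_reproducibility_study(seed = 1)
  .study_cache$repro
}

default_furosemide_report <- function() {
  if (is.null(.study_cache$furo))
    .study_cache$furo <- run_furosemide_study(seed = 1)
  .study_cache$furo
}
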