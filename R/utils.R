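#' @useDynLib nephna, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm optimize pchisq pnorm pt rnorm sd kruskal.test p.adjust
#' @importFrom utils combn
NULL

# Derive a reproducible sub-seed from a root seed and a stream label, so that
# independent randomness sources (anatomy, noise, serum, ...) never share a
# stream. Lehmer-style mixing, kept strictly below 2^31 - 1.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483629
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 131 + ch) %% m
  s <- (abs(as.double(seed)) %% m)
  as.integer((s * 48271 + h * 16807 + 12345) %% m)
}

# Run `expr` with a local RNG state seeded at `seed`; restores the caller's
# RNG so generators never perturb user code.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_data <- function(...) stop(..., call. = FALSE)

check_prob_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x >= 1)
    stop_data(name, " must be a single value in [0, 1)")
  invisible(x)
}
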