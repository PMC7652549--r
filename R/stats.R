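stat_result <- function(method, statistic, p_value, n, exact,
                        flag = NA_character_) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(method = method, statistic = unname(statistic),
                 p_value = unname(p_value), n = n, exact = exact,
                 flag = flag),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g, n = %d (%s)%s\n",
              x$method, x$statistic, x$p_value, x$n,
              if (isTRUE(x$exact)) "exact" else "approximate",
              if (is.na(x$flag)) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

# two-sided p from an enumerated null distribution of a statistic
two_sided_from_null <- function(null_values, observed) {
  lo <- mean(null_values <= observed + 1e-9)
  hi <- mean(null_values >= observed - 1e-9)
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test of the paired difference `a - b`. For `n <= exact_limit`
#' nonzero differences the null is the exact permutation distribution over
#' all 2^n sign assignments of the midranks (so ties are handled exactly);
#' zero differences are dropped in exact mode. Beyond the limit a normal
#' approximation with tie correction is used, handling zeros by Pratt's
#' method (zeros are ranked, then discarded from the statistic).
#'
#' @param paired_a,paired_b equal-length numeric vectors (>= 3 pairs).
#' @param exact_limit largest n for which the exact null is enumerated.
#' @return A `stat_result` with the V statistic (sum of positive-difference
#'   ranks) and two-sided p. All differences zero gives statistic 0, p = 1,
#'   flagged `"degenerate"`.
#' @examples
#' wilcoxon_signed_rank(c(92, 90, 95, 91, 94, 93), c(70, 69, 72, 68, 71, 70))
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b,
                                 exact_limit = 12L) {
  if (length(paired_a) != length(paired_b))
    stop_data("paired samples must have equal length")
  if (length(paired_a) < 3L) stop_data("need at least 3 pairs")
  d <- paired_a - paired_b
  if (all(d == 0))
    return(stat_result("wilcoxon_signed_rank", 0, 1, length(d), TRUE,
                       flag = "degenerate"))
  nz <- d[d != 0]
  n <- length(nz)
  if (n <= exact_limit) {
    r <- rank(abs(nz))
    v_obs <- sum(r[nz > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    null_v <- as.vector(signs %*% r)
    p <- two_sided_from_null(null_v, v_obs)
    stat_result("wilcoxon_signed_rank", v_obs, p, n, TRUE)
  } else {
    # Pratt: rank |d| including zeros, drop zeros from the statistic
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    nn <- length(d)
    mu <- nn * (nn + 1) / 4 - sum(r[d == 0]) / 2
    ties <- table(r[d != 0])
    sig2 <- nn * (nn + 1) * (2 * nn + 1) / 24 -
      sum(r[d == 0]^2) / 4 - sum(ties^3 - ties) / 48
    z <- (v_obs - mu) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    stat_result("wilcoxon_signed_rank", v_obs, p, n, FALSE)
  }
}

#' Rank-sum (Mann-Whitney) test for two independent groups
#'
#' Two-sided test of a location difference. For combined
#' `n <= exact_limit` the null is enumerated exactly over all
#' `choose(n, n_a)` group assignments of the midranks (ties exact);
#' otherwise a tie-corrected normal approximation is used.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @param exact_limit largest combined n for exact enumeration.
#' @return A `stat_result` with the rank-sum W of `group_a` as statistic.
#' @export
rank_sum <- function(group_a, group_b, exact_limit = 12L) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop_data("both groups need at least 2 values")
  n <- na + nb
  r <- rank(c(group_a, group_b))
  w_obs <- sum(r[seq_len(na)])
  if (n <= exact_limit) {
    splits <- combn(n, na)
    null_w <- colSums(matrix(r[splits], nrow = na))
    p <- two_sided_from_null(null_w, w_obs)
    stat_result("rank_sum", w_obs, p, n, TRUE)
  } else {
    mu <- na * (n + 1) / 2
    ties <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sig2 <= 0)
      return(stat_result("rank_sum", w_obs, 1, n, FALSE, flag = "degenerate"))
    z <- (w_obs - mu) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    stat_result("rank_sum", w_obs, p, n, FALSE)
  }
}

#' Kruskal-Wallis rank test across several groups
#'
#' Tie-corrected H statistic with a chi-square p-value on k - 1 degrees of
#' freedom (delegating to [stats::kruskal.test()]). Used as the gatekeeper
#' before pairwise region comparisons.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @return A `stat_result`; all-identical constant groups give H = 0,
#'   p = 1, flagged `"degenerate"`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_data("need a list of at least 2 groups")
  if (any(lengths(groups) < 2L)) stop_data("every group needs >= 2 values")
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L)
    return(stat_result("kruskal_wallis", 0, 1,
                       length(x), FALSE, flag = "degenerate"))
  kt <- kruskal.test(groups)
  stat_result("kruskal_wallis", kt$statistic, kt$p.value, length(x), FALSE)
}

#' Bonferroni adjustment with an explicit family size
#'
#' `p_adj = min(1, m * p)` for a family of `m` comparisons (which may
#' exceed the number of p-values supplied).
#'
#' @param p_values numeric vector of p-values.
#' @param m family size; `m >= length(p_values)`.
#' @return Adjusted p-values, never smaller than the input.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (m < length(p_values))
    stop_data("family size m must be at least the number of p-values")
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_data("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "bonferroni", n = m)
}

#' Coefficient of variation, percent
#'
#' `100 * sample SD / mean`; the reproducibility metric across subjects
#' within a site.
#'
#' @param values numeric vector, n >= 2, nonzero mean.
#' @return CoV in percent.
#' @examples
#' cov_percent(c(90, 100, 110)) # 10
#' @export
cov_percent <- function(values) {
  if (length(values) < 2L) stop_data("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop_data("coefficient of variation undefined for zero mean")
  100 * sd(values) / m
}

#' Ordinary least-squares line with R-squared and slope p-value
#'
#' @param x,y numeric vectors of equal length (>= 3 for the p-value);
#'   `x` must not be constant. A zero-variance response is reported as
#'   slope 0, R-squared 0, p = 1 (not NaN), keeping result tables total.
#' @return A list of class `linear_fit`: `slope`, `intercept`,
#'   `r_squared` (squared Pearson correlation), `p_value` (slope t-test,
#'   two-sided; NA for n < 3), `n`.
#' @export
linear_fit_r2 <- function(x, y) {
  if (length(x) != length(y)) stop_data("x and y must have equal length")
  if (length(unique(x)) < 2L) stop_data("x is constant; no line can be fitted")
  fit <- lm(y ~ x)
  cf <- coef(fit)
  n <- length(x)
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    # zero-variance response: define R2 = 0 (not NaN) to keep tables total
    return(structure(list(slope = 0, intercept = mean(y), r_squared = 0,
                          p_value = 1, n = n), class = "linear_fit"))
  }
  r2 <- 1 - ssr / sst
  p <- NA_real_
  if (n >= 3) {
    se <- sqrt(ssr / (n - 2) / sum((x - mean(x))^2))
    p <- if (se == 0) 0 else 2 * pt(-abs(cf[[2]] / se), df = n - 2)
  }
  structure(list(slope = cf[[2]], intercept = cf[[1]], r_squared = r2,
                 p_value = unname(p), n = n), class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope %.4g, intercept %.4g, R2 = %.4f, p = %.3g (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}
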