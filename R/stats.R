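# Cohort statistics in the reporting convention used for the synthesis
# tables: mean +/- sample SD with a Student-t 95% CI, and paired two-sided
# Wilcoxon signed-rank tests (exact under ties for small samples).

#' Confidence interval from summary moments
#'
#' `mean +/- t_{1-alpha/2, n-1} * sd / sqrt(n)`. The Student-t critical
#' value (not the normal z) together with the sample (n-1 denominator) SD is
#' the convention that reproduces the published per-cohort intervals from
#' their printed means and SDs.
#'
#' @param mean,sd Summary moments (sd with n-1 denominator).
#' @param n Subject count (>= 2).
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(ci_low, ci_high)`.
#' @export
ci_from_moments <- function(mean, sd, n, level = 0.95) {
  if (n < 2) stop("need n >= 2")
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd / sqrt(n)
  c(ci_low = mean - half, ci_high = mean + half)
}

#' Summarize a per-subject metric
#'
#' @param values Numeric vector of per-subject values (n >= 2).
#' @param level Confidence level.
#' @return A `cohort_summary`: list with `n`, `mean`, `sd`, `ci_low`,
#'   `ci_high`, `level`.
#' @export
summarize_cohort <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least two non-missing values")
  m <- mean(values)
  s <- sd(values)
  ci <- ci_from_moments(m, s, n, level)
  structure(list(n = n, mean = m, sd = s, ci_low = unname(ci[1]),
                 ci_high = unname(ci[2]), level = level),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("%.2f (+/- %.2f) [%.2f, %.2f]  (n = %d, %d%% CI)\n",
              x$mean, x$sd, x$ci_low, x$ci_high, x$n, round(100 * x$level)))
  invisible(x)
}

# Exact null distribution of the signed-rank statistic V (sum of ranks of
# positive differences) under possibly tied average ranks, by dynamic
# programming over doubled (hence integer) ranks. Returns P(V2 = v) on the
# doubled scale 0..sum(2*ranks).
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g / 2
  }
  f
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Zero differences are dropped; absolute differences are ranked with
#' average ranks under ties. For at most `exact_max` non-zero differences
#' the two-sided p-value is computed from the exact null distribution of the
#' signed-rank sum (equivalent to enumerating all 2^m sign assignments,
#' including tied ranks); otherwise a normal approximation with tie
#' correction and a 0.5 continuity correction is used. Two-sided p is
#' `min(1, 2 * min(P(V <= v), P(V >= v)))`.
#'
#' @param a,b Paired per-subject values of equal length.
#' @param exact_max Largest number of non-zero differences for the exact
#'   branch (default 25).
#' @return List with `p_value`, `statistic` (V), `n_effective`, `method`.
#' @export
paired_wilcoxon <- function(a, b, exact_max = 25L) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) stop("all differences are zero: test undefined")
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (m <= exact_max) {
    ranks2 <- as.integer(round(2 * r))
    null <- signed_rank_null(ranks2)
    v2 <- as.integer(round(2 * v))
    p_le <- sum(null[seq_len(v2 + 1)])
    p_ge <- sum(null[(v2 + 1):length(null)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- m * (m + 1) / 4
    sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation (tie + continuity corrected)"
  }
  list(p_value = p, statistic = v, n_effective = m, method = method)
}
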