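#' Pearson correlation with input validation
#'
#' Sample Pearson product-moment correlation, used for the radial-fraction
#' vs closure-velocity cohort relationship.
#'
#' @param x,y numeric vectors of equal length, n >= 3, each with nonzero
#'   variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("need at least 3 observations.")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    abort("zero variance in `x` or `y`.")
  }
  stats::cor(x, y, method = "pearson")
}

#' Mann-Whitney rank-sum test
#'
#' Two-sample rank-sum comparison. For small untied samples
#' (`min(nA, nB) <= 8` and `nA + nB <= 20`) the null distribution of the U
#' statistic is enumerated exactly by the standard counting recursion and
#' the two-sided p doubles the smaller tail (capped at 1). Otherwise a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param a,b numeric vectors (both nonempty).
#' @return One-row tibble: `u` (U statistic of `a`), `p_value`, `method`
#'   (`"exact"` or `"normal"`).
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) abort("both groups must be nonempty.")
  m <- length(a)
  n <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_a <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (!has_ties && min(m, n) <= 8L && m + n <= 20L) {
    counts <- mw_counts(m, n)
    total <- sum(counts)
    p_lo <- sum(counts[seq_len(u_a + 1L)]) / total
    p_hi <- sum(counts[(u_a + 1L):length(counts)]) / total
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- m * n / 2
    nt <- table(pooled)
    tie_term <- sum(nt^3 - nt) / ((m + n) * (m + n - 1))
    sigma <- sqrt(m * n / 12 * ((m + n + 1) - tie_term))
    z <- u_a - mu
    z <- (z - sign(z) * 0.5) / sigma # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  tibble(u = u_a, p_value = p, method = method)
}

# Counts of the exact Mann-Whitney U null distribution for sample sizes
# (m, n): N(m, n; u) = N(m-1, n; u-n) + N(m, n-1; u). Returns the vector
# of counts for u = 0..m*n (sums to choose(m+n, m)).
mw_counts <- function(m, n) {
  memo <- new.env(parent = emptyenv())
  rec <- function(m, n) {
    if (m == 0L || n == 0L) return(1)
    key <- paste(m, n)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    a <- rec(m - 1L, n)
    b <- rec(m, n - 1L)
    out <- numeric(m * n + 1L)
    out[(n + 1L):(n + length(a))] <- a
    out[seq_along(b)] <- out[seq_along(b)] + b
    memo[[key]] <- out
    out
  }
  rec(as.integer(m), as.integer(n))
}
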