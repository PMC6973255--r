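#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test of association in a 2x2 contingency table, computed
#' by summing hypergeometric point probabilities over all tables sharing the
#' observed margins. The two-sided p-value uses the point-probability
#' ordering: every table whose probability does not exceed that of the
#' observed table (up to a relative tolerance of 1e-7, guarding against
#' floating-point ties) contributes. This is the most common two-sided
#' convention for the test.
#'
#' In this package the table rows are the two alleles of the SNP linked to a
#' repeat marker and the columns are deleted / not-deleted read counts, so the
#' p-value measures allelic bias of repeat deletions -- evidence that
#' deletions are somatic rather than polymerase stutter.
#'
#' @param x A 2x2 matrix of non-negative counts, or a numeric vector of
#'   length 4 interpreted row-wise as `c(a, b, c, d)`.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`;
#'   one-sided variants condition on the same margins and sum the
#'   corresponding hypergeometric tail (for sensitivity analyses only).
#' @return A p-value in `[0, 1]`. A table with a zero row or column margin is
#'   uninformative and returns 1.
#' @examples
#' fisher_exact2(matrix(c(5, 5, 5, 5), 2))   # balanced -> 1
#' fisher_exact2(c(10, 0, 0, 10))            # maximal association
#' @export
fisher_exact2 <- function(x, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  x <- as.integer(round(as.vector(x)))
  if (length(x) != 4L || any(is.na(x)) || any(x < 0L))
    stop("'x' must be four non-negative counts (2x2 table)")
  a <- x[1L]; b <- x[2L]; cc <- x[3L]; d <- x[4L]
  m <- a + b          # row 1 margin
  n <- cc + d         # row 2 margin
  k <- a + cc         # column 1 margin
  if (m == 0L || n == 0L || k == 0L || (b + d) == 0L) return(1)
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  # P(A = i) with margins fixed: hypergeometric(m, n, k)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- probs[match(a, support)]
  p <- switch(alternative,
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    less      = sum(probs[support <= a]),
    greater   = sum(probs[support >= a]))
  min(1, p)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion by beta tail inversion.
#' For `x = n` the lower bound is `(alpha/2)^(1/n)` and the upper bound 1;
#' for `x = 0` the lower bound is 0. Used to report exact confidence
#' intervals on classifier sensitivity and specificity.
#'
#' @param x Number of successes (0 <= x <= n).
#' @param n Number of trials (>= 1).
#' @param conf Confidence level, default 0.95.
#' @return Named numeric vector `c(lower, upper)` of proportions.
#' @examples
#' clopper_pearson(51, 51)   # lower bound 0.930
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("'n' must be a positive integer")
  if (length(x) != 1L || is.na(x) || x < 0 || x > n) stop("'x' must be in [0, n]")
  alpha <- 1 - conf
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' 95th percentile of training deletion frequencies
#'
#' Percentile estimator used to dichotomize a sample's per-marker deletion
#' frequency: the classifier's threshold for a marker is the 95th percentile
#' of the deletion frequencies observed in the microsatellite-stable (MSS)
#' training samples. The convention is linear interpolation between order
#' statistics at fractional rank `0.95 * (n - 1) + 1` (the default, type-7
#' quantile definition of [stats::quantile()]).
#'
#' @param values Numeric vector of proportions, length >= 2.
#' @return The 95th percentile, a value in the range of `values`.
#' @examples
#' percentile_95(seq(0.01, 0.20, by = 0.01))  # 0.1905
#' @export
percentile_95 <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    stop("at least 2 values are required to estimate the 95th percentile")
  unname(stats::quantile(values, probs = 0.95, type = 7))
}
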