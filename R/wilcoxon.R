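#' Exact Wilcoxon matched-pairs signed-rank test
#'
#' Paired two-sided test on within-subject differences, exact for the small
#' cohorts this analysis targets (n of about 10). Zero differences are
#' dropped; ties in |d| receive average ranks. The statistic is
#' `W = min(W+, W-)`, the smaller of the positive- and negative-rank sums.
#' The two-sided p-value is the null probability, over all `2^n` equally
#' likely sign assignments, that `min(W+, W-)` is at most the observed value.
#' The distribution is computed by exact convolution over the (tie-averaged)
#' ranks, which enumerates all sign assignments implicitly and handles tied
#' ranks exactly.
#'
#' @param x,y paired numeric vectors of equal length (3 to 25 pairs).
#' @return An object of class `htest` with the statistic `W`, the rank sums
#'   `W+` and `W-` (reported in `parameter`), the number of non-zero pairs
#'   `n`, and the exact two-sided `p.value`.
#' @examples
#' wilcoxon_exact(c(5, 6, 7, 8, 9), c(1, 2, 3, 4, 4.5))  # p = 2/32
#' @export
wilcoxon_exact <- function(x, y) {
  if (length(x) != length(y))
    crc_stop("crc_bad_argument", "'x' and 'y' must have equal length")
  if (length(x) < 3L || length(x) > 25L)
    crc_stop("crc_bad_argument", "need between 3 and 25 pairs, got %d", length(x))
  d <- as.numeric(x) - as.numeric(y)
  if (anyNA(d))
    crc_stop("crc_bad_argument", "missing values in paired data")
  d <- d[d != 0]
  if (length(d) == 0L)
    crc_stop("crc_degenerate_test", "all paired differences are zero")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  # doubled ranks are integers even with .5 average ranks
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  f <- numeric(total + 1L)   # f[s+1] = #assignments with doubled W+ == s
  f[1L] <- 1
  for (rk in r2) {
    shifted <- c(numeric(rk), f[seq_len(total + 1L - rk)])
    f <- f + shifted
  }
  probs <- f / 2^length(d)
  s <- 0:total
  p <- sum(probs[pmin(s, total - s) <= round(2 * w) + 1e-9])
  structure(list(
    statistic = c(W = w),
    parameter = c(`W+` = w_plus, `W-` = w_minus, n = length(d)),
    p.value = min(p, 1),
    method = "Exact Wilcoxon matched-pairs signed-rank test (two-sided)",
    alternative = "two.sided",
    data.name = paste(deparse(substitute(x)), "vs", deparse(substitute(y)))
  ), class = "htest")
}
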