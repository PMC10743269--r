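#' Common binning specification for paired R-R / IBI samples
#'
#' Builds equal-width bin edges per variable spanning the pooled range of the
#' bradycardic and non-bradycardic values of one subject-trial, so both
#' conditions share a common alphabet and condition differences reflect
#' distribution shape, not support. The rightmost edge is inclusive.
#'
#' @param rr_all,ibi_all all (pooled B + NB) R-R and IBI values of the
#'   subject-trial, seconds.
#' @param n_bins number of bins per variable (>= 2); default 16, bounding each
#'   marginal entropy by 4 bits.
#' @return An object of class `binning_spec`: list with `n_bins`, `edges_rr`,
#'   `edges_ibi`.
#' @export
make_binning <- function(rr_all, ibi_all, n_bins = 16L) {
  if (length(rr_all) == 0L || length(ibi_all) == 0L)
    crc_stop("crc_bad_argument", "value vectors must be non-empty")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 2L)
    crc_stop("crc_bad_argument", "'n_bins' must be >= 2")
  edges1 <- function(x, what) {
    lo <- min(x); hi <- max(x)
    if (!is.finite(lo) || !is.finite(hi) || lo == hi)
      crc_stop("crc_degenerate_data",
               "degenerate %s range [%g, %g]: cannot bin", what, lo, hi)
    seq(lo, hi, length.out = n_bins + 1L)
  }
  structure(list(n_bins = n_bins,
                 edges_rr = edges1(rr_all, "RR"),
                 edges_ibi = edges1(ibi_all, "IBI")),
            class = "binning_spec")
}

# bin indices with left-closed right-open bins, last bin closed;
# errors on out-of-range values
bin_index <- function(values, edges) {
  if (any(values < edges[1] - 1e-12) || any(values > edges[length(edges)] + 1e-12))
    crc_stop("crc_out_of_range", "value outside binning range [%g, %g]",
             edges[1], edges[length(edges)])
  idx <- findInterval(values, edges, rightmost.closed = TRUE, all.inside = FALSE)
  pmin(pmax(idx, 1L), length(edges) - 1L)
}

#' Empirical probability distribution from binned values
#'
#' Counts per bin divided by the total. Bins are left-closed and right-open,
#' except the last bin which also includes the right edge.
#'
#' @param values numeric values, all within `[edges[1], edges[length(edges)]]`.
#' @param edges strictly increasing bin edges.
#' @return An object of class `prob_dist`: list with probability vector `p`,
#'   integer `counts` and `n_samples`.
#' @examples
#' hist_prob(c(0.35, 0.45, 0.45, 0.65), seq(0.3, 0.7, by = 0.1))$p
#' @export
hist_prob <- function(values, edges) {
  if (length(edges) < 3L || !is_strictly_increasing(edges))
    crc_stop("crc_bad_argument", "'edges' must be >= 3 strictly increasing values")
  counts <- tabulate(bin_index(values, edges), nbins = length(edges) - 1L)
  prob_dist(counts)
}

#' Construct a probability distribution from bin counts
#' @param counts non-negative integer counts per bin.
#' @return A `prob_dist` object.
#' @export
prob_dist <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || sum(counts) <= 0)
    crc_stop("crc_bad_argument", "counts must be non-negative with positive total")
  structure(list(p = counts / sum(counts), counts = counts,
                 n_samples = sum(counts)),
            class = "prob_dist")
}

#' Shannon entropy of a binned distribution, in bits
#'
#' Plug-in estimator \eqn{H = -\sum_i p_i \log_2 p_i} with the convention
#' \eqn{0 \log_2 0 = 0}. Bounded by `log2(n_bins)`.
#'
#' @param d a [prob_dist] (or bare probability vector summing to 1).
#' @return Entropy in bits.
#' @examples
#' shannon_entropy(prob_dist(rep(1, 8)))  # 3 bits
#' @export
shannon_entropy <- function(d) {
  p <- if (inherits(d, "prob_dist")) d$p else as.numeric(d)
  if (abs(sum(p) - 1) > 1e-9 || any(p < 0))
    crc_stop("crc_bad_argument", "probabilities must be non-negative and sum to 1")
  entropy_bits(p)
}

#' Cross-entropy between two binned distributions, in bits
#'
#' \eqn{cH(P, Q) = -\sum_i p_i \log_2 q_i} over a common alphabet paired by
#' bin index (for R-R vs IBI this pairs the i-th R-R bin with the i-th IBI
#' bin). Asymmetric in its arguments. When `q` has an empty bin where
#' `p_i > 0` the sum is infinite; only in that case `q` is smoothed with
#' Jeffreys pseudo-counts (0.5 added to each bin count, then renormalised).
#' With no empty-bin collision `q` is used as is, so `cross_entropy(p, p)`
#' equals `shannon_entropy(p)` whenever `p` has no empty bins.
#'
#' @param p,q [prob_dist] objects with the same number of bins.
#' @return Cross-entropy in bits.
#' @export
cross_entropy <- function(p, q) {
  if (!inherits(p, "prob_dist") || !inherits(q, "prob_dist"))
    crc_stop("crc_bad_argument", "'p' and 'q' must be prob_dist objects")
  if (length(p$p) != length(q$p))
    crc_stop("crc_alphabet_error",
             "mismatched alphabets: %d vs %d bins", length(p$p), length(q$p))
  qq <- q$p
  if (any(p$p > 0 & qq == 0))
    qq <- (q$counts + 0.5) / (q$n_samples + 0.5 * length(q$counts))
  i <- p$p > 0
  -sum(p$p[i] * log2(qq[i]))
}

#' Joint probability distribution of paired R-R / IBI samples
#'
#' Two-dimensional histogram of the paired grid samples on the shared binning,
#' normalised to total 1. Row sums reproduce the marginal R-R distribution and
#' column sums the marginal IBI distribution built from the same samples and
#' edges.
#'
#' @param rr_values,ibi_values paired value vectors, equal length.
#' @param spec a [make_binning()] specification.
#' @return An object of class `joint_prob_dist`: list with matrix `p_xy`
#'   (rr-bin x ibi-bin), `counts` and `n_samples`.
#' @export
joint_hist_prob <- function(rr_values, ibi_values, spec) {
  if (length(rr_values) != length(ibi_values))
    crc_stop("crc_pairing_error", "rr and ibi values must be paired (equal length)")
  if (!inherits(spec, "binning_spec"))
    crc_stop("crc_bad_argument", "'spec' must be a binning_spec")
  bx <- bin_index(rr_values, spec$edges_rr)
  by <- bin_index(ibi_values, spec$edges_ibi)
  nb <- spec$n_bins
  counts <- matrix(tabulate((by - 1L) * nb + bx, nbins = nb * nb), nrow = nb)
  structure(list(p_xy = counts / sum(counts), counts = counts,
                 n_samples = length(rr_values)),
            class = "joint_prob_dist")
}

#' Mutual information from a joint distribution, in bits
#'
#' Plug-in estimator \eqn{MI(X, Y) = H(X) + H(Y) - H(X, Y)} with all entropies
#' computed by the base-2 Shannon formula on the joint histogram's marginals
#' and cells. Non-negative up to rounding and bounded by
#' `min(H(X), H(Y))`. No small-sample bias correction is applied; the
#' positive finite-sample bias of the plug-in estimator is shared by both
#' conditions when sample counts are balanced.
#'
#' @param j a [joint_hist_prob()] result.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(j) {
  if (!inherits(j, "joint_prob_dist"))
    crc_stop("crc_bad_argument", "'j' must be a joint_prob_dist")
  hx <- entropy_bits(rowSums(j$p_xy))
  hy <- entropy_bits(colSums(j$p_xy))
  hxy <- entropy_bits(as.vector(j$p_xy))
  hx + hy - hxy
}
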