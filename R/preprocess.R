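#' Parameters of the interval preprocessing stage
#'
#' Controls recognition-error removal, the adaptive replacement filter and the
#' plausibility bounds applied to R-R and inter-breath interval series.
#'
#' The adaptive filter maintains a running mean \eqn{\mu_a} and standard
#' deviation \eqn{\sigma_a} updated exponentially over accepted samples
#' (`x_new = (1 - c) x_old + c * sample`, `c = adapt_coeff`). A sample is an
#' outlier if it jumps by more than `percent_limit` relative to the previous
#' output value (percent filter) or deviates from \eqn{\mu_a} by more than
#' `sigma_mult` \eqn{\sigma_a} (controlling filter); outliers are replaced by a
#' uniform draw from \eqn{[\mu_a - 0.5\sigma_a, \mu_a + 0.5\sigma_a]}, the
#' source of trial-to-trial variability in the repeated-trial protocol.
#'
#' The default `percent_limit` of 0.5 is chosen so that the filter catches
#' gross annotation artifacts (a missed beat doubles the local R-R) while
#' passing physiological respiratory modulation of the heart period, whose
#' beat-to-beat swings scale with the modulation depth and can be large in
#' strongly coupled records.
#'
#' @param adapt_coeff exponential update weight `c`, in (0, 1).
#' @param percent_limit fractional beat-to-beat jump flagged by the percent
#'   filter (dimensionless, > 0).
#' @param sigma_mult multiple of the adaptive standard deviation flagged by the
#'   controlling filter (> 0).
#' @param rr_bounds,ibi_bounds plausibility ranges in seconds; intervals outside
#'   are treated as recognition errors and removed.
#' @return An object of class `filter_params`.
#' @seealso [remove_recognition_errors()], [adaptive_filter()]
#' @export
filter_params <- function(adapt_coeff = 0.05, percent_limit = 0.5,
                          sigma_mult = 3.0,
                          rr_bounds = c(0.2, 2.0), ibi_bounds = c(0.3, 15)) {
  stopifnot_scalar_num(adapt_coeff, "adapt_coeff")
  if (adapt_coeff <= 0 || adapt_coeff >= 1)
    crc_stop("crc_bad_argument", "'adapt_coeff' must be in (0, 1)")
  stopifnot_scalar_num(percent_limit, "percent_limit", positive = TRUE)
  stopifnot_scalar_num(sigma_mult, "sigma_mult", positive = TRUE)
  for (b in list(rr_bounds = rr_bounds, ibi_bounds = ibi_bounds)) {
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2])
      crc_stop("crc_bad_argument", "bounds must be an increasing pair of numbers")
  }
  structure(list(adapt_coeff = adapt_coeff, percent_limit = percent_limit,
                 sigma_mult = sigma_mult, rr_bounds = rr_bounds,
                 ibi_bounds = ibi_bounds),
            class = "filter_params")
}

bounds_for <- function(params, kind) {
  if (kind == "RR") params$rr_bounds else params$ibi_bounds
}

#' Remove evident recognition errors from an interval series
#'
#' Deletes (does not replace) intervals that cannot be physiological: values
#' <= 0 (zero-length intervals) and values outside the plausibility bounds for
#' the series kind (pauses, gross annotation gaps). Removing more than 20% of
#' the samples raises a quality warning; an empty result is an error.
#'
#' @param s an [interval_series].
#' @param params a [filter_params] object supplying the plausibility bounds.
#' @return The cleaned [interval_series]; the number of removed samples is
#'   attached as attribute `"n_removed"`.
#' @export
remove_recognition_errors <- function(s, params = filter_params()) {
  if (!inherits(s, "interval_series"))
    crc_stop("crc_bad_argument", "'s' must be an interval_series")
  b <- bounds_for(params, s$kind)
  keep <- s$values > 0 & s$values >= b[1] & s$values <= b[2]
  n_rm <- sum(!keep)
  if (all(!keep))
    crc_stop("crc_insufficient_data",
             "all %d samples removed as recognition errors (%s)", length(keep), s$kind)
  if (n_rm > 0.2 * length(keep))
    crc_warn("crc_quality_warning",
             "removed %d/%d samples (%.0f%%) from %s series as recognition errors",
             n_rm, length(keep), 100 * n_rm / length(keep), s$kind)
  out <- interval_series(s$times[keep], s$values[keep], s$kind, s$subject_id)
  attr(out, "n_removed") <- n_rm
  out
}

#' Adaptive replacement filtering of interval outliers
#'
#' Streaming two-stage outlier filter for tachogram-like series. A running
#' adaptive mean \eqn{\mu_a} and standard deviation \eqn{\sigma_a} are
#' initialised from the first 20 samples and updated exponentially with every
#' incoming sample, so the filter tracks sustained physiological shifts such
#' as a bradycardic deceleration instead of rejecting them indefinitely.
#' Sample `k` is an outlier if either
#' \itemize{
#'   \item percent filter: `|v[k] - v[k-1]| > percent_limit * v[k-1]`, where
#'     `v[k-1]` is the previous input value, or
#'   \item controlling filter: `|v[k] - mu_a| > sigma_mult * sigma_a`.
#' }
#' Outliers are replaced by a uniform random draw from
#' \eqn{[\mu_a - 0.5\sigma_a, \mu_a + 0.5\sigma_a]} evaluated at the moment of
#' replacement. Both criteria and the adaptive statistics depend only on the
#' input values, never on the random replacements, so which positions are
#' replaced is deterministic; two runs with different seeds differ only at the
#' replaced positions. The output has the same length and time stamps as the
#' input. Draws come from R's current random stream: seed the session (or the
#' enclosing trial) for reproducibility. On a series where no sample trips
#' either criterion the output equals the input exactly and no random numbers
#' are consumed.
#'
#' @param s an [interval_series], at least 10 samples.
#' @param params a [filter_params] object.
#' @return The filtered [interval_series]. Attribute `"replacements"` is a
#'   data.frame with one row per replaced sample (`index`, `original`,
#'   `replacement`, `mu_a`, `sigma_a` at the moment of replacement).
#' @export
adaptive_filter <- function(s, params = filter_params()) {
  if (!inherits(s, "interval_series"))
    crc_stop("crc_bad_argument", "'s' must be an interval_series")
  v <- s$values
  n <- length(v)
  if (n < 10L)
    crc_stop("crc_insufficient_data",
             "adaptive_filter needs >= 10 samples, got %d", n)
  cc <- params$adapt_coeff
  k0 <- min(20L, n)
  mu0 <- mean(v[seq_len(k0)])
  sig0 <- stats::sd(v[seq_len(k0)])
  # the adaptive statistics depend only on the input values, so the
  # exponential recursions unroll to linear filters; mu_lag/sig_lag are the
  # statistics in force when sample k is tested (i.e. before absorbing it)
  mu_seq <- as.numeric(stats::filter(cc * v, 1 - cc, method = "recursive",
                                     init = mu0))
  sig2_seq <- as.numeric(stats::filter(cc * (v - mu_seq)^2, 1 - cc,
                                       method = "recursive", init = sig0^2))
  mu_lag <- c(mu0, mu_seq[-n])
  sig_lag <- c(sig0, sqrt(sig2_seq[-n]))
  pct_out <- c(FALSE, abs(diff(v)) > params$percent_limit * v[-n])
  ctl_out <- abs(v - mu_lag) > params$sigma_mult * sig_lag
  idx <- which(pct_out | ctl_out)
  out <- v
  if (length(idx)) {
    out[idx] <- stats::runif(length(idx),
                             mu_lag[idx] - 0.5 * sig_lag[idx],
                             mu_lag[idx] + 0.5 * sig_lag[idx])
  }
  res <- interval_series(s$times, out, s$kind, s$subject_id)
  attr(res, "replacements") <- data.frame(
    index = idx, original = v[idx], replacement = out[idx],
    mu_a = mu_lag[idx], sigma_a = sig_lag[idx])
  res
}

#' Uniformly resampled interval series
#'
#' Interval values evaluated on a fixed-rate time grid `t0 + k/fs`. The paired
#' R-R and IBI series of one subject are resampled on the identical grid so
#' that samples are synchronous.
#'
#' @param values interval values (seconds) at each grid point.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first grid point, seconds.
#' @param kind `"RR"` or `"IBI"`.
#' @param subject_id subject label.
#' @return An object of class `uniform_series`.
#' @export
uniform_series <- function(values, fs, t0, kind = c("RR", "IBI"), subject_id = "") {
  kind <- match.arg(kind)
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  stopifnot_scalar_num(t0, "t0")
  structure(list(values = as.numeric(values), fs = fs, t0 = t0, kind = kind,
                 subject_id = as.character(subject_id)),
            class = "uniform_series")
}

#' Grid times of a uniform series
#' @param u a [uniform_series].
#' @return Numeric vector `t0 + (0:(n-1))/fs`.
#' @export
grid_times <- function(u) {
  u$t0 + (seq_along(u$values) - 1L) / u$fs
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %s @ %g Hz: n = %d, t0 = %.2f s\n",
              x$kind, x$fs, length(x$values), x$t0))
  invisible(x)
}

#' Resample an interval series on a uniform grid
#'
#' Interpolates the non-equidistant (time, value) samples of an interval series
#' onto the grid `t_start + k/fs`, `k = 0 .. floor((t_end - t_start) * fs)`.
#' The default interpolant is the shape-preserving (monotone Fritsch-Carlson)
#' piecewise cubic, which cannot overshoot below the local data range near
#' bradycardia steps; `method = "linear"` is available as an alternative.
#'
#' @param s an [interval_series] with at least 4 samples whose time span covers
#'   `[t_start, t_end]`.
#' @param fs grid rate in Hz (default 4).
#' @param t_start,t_end grid limits in seconds; default to the series span.
#' @param method `"pchip"` (shape-preserving cubic) or `"linear"`.
#' @return A [uniform_series].
#' @export
resample_uniform <- function(s, fs = 4, t_start = NULL, t_end = NULL,
                             method = c("pchip", "linear")) {
  if (!inherits(s, "interval_series"))
    crc_stop("crc_bad_argument", "'s' must be an interval_series")
  method <- match.arg(method)
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  if (is.null(t_start)) t_start <- s$times[1]
  if (is.null(t_end)) t_end <- s$times[length(s$times)]
  if (length(s$times) < 4L)
    crc_stop("crc_insufficient_data",
             "resampling needs >= 4 samples, got %d", length(s$times))
  if (t_start >= t_end)
    crc_stop("crc_bad_argument", "t_start must be < t_end")
  eps <- 1e-9
  if (t_start < s$times[1] - eps || t_end > s$times[length(s$times)] + eps)
    crc_stop("crc_extrapolation_error",
             "grid [%.3f, %.3f] outside data span [%.3f, %.3f]",
             t_start, t_end, s$times[1], s$times[length(s$times)])
  grid <- t_start + (0:floor((t_end - t_start) * fs + eps)) / fs
  vals <- switch(method,
    pchip = stats::splinefun(s$times, s$values, method = "monoH.FC")(grid),
    linear = stats::approx(s$times, s$values, xout = grid, rule = 1)$y)
  uniform_series(vals, fs = fs, t0 = t_start, kind = s$kind,
                 subject_id = s$subject_id)
}
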