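#' Flag bradycardic intervals in a beat-wise R-R series
#'
#' Neonatal bradycardia is operationalised as a heart rate below 100 bpm
#' (R-R >= 0.6 s) sustained for at least two beats (a pair of intervals
#' spanning >= 1.2 s). Interval `k` is flagged when `v[k] >= rr_threshold` and
#' the sum of `v[k]` with at least one neighbouring interval reaches
#' `pair_sum`: the first interval can only pair with its successor, the last
#' only with its predecessor, interior intervals with either. An isolated long
#' interval surrounded by short ones is therefore never flagged, and no
#' interval below `rr_threshold` is ever flagged.
#'
#' The rule is evaluated on the original beat-wise series (after filtering),
#' not on the resampled grid: "lasts at least two beats" is a beat-domain
#' statement. Labels reach the grid via [flags_to_spans()] and [label_grid()].
#'
#' @param rr an [interval_series] of kind `"RR"` with at least 2 intervals.
#' @param rr_threshold bradycardia threshold in seconds (default 0.6, i.e.
#'   100 bpm).
#' @param pair_sum minimum two-beat span in seconds (default 1.2).
#' @return An object of class `beat_flag_series`: list with `times`, `values`
#'   and logical `flags`, one per interval.
#' @examples
#' rr <- interval_series(times = cumsum(c(0.5, 0.7, 0.7, 0.5)),
#'                       values = c(0.5, 0.7, 0.7, 0.5), kind = "RR")
#' flag_bradycardia(rr)$flags   # F T T F
#' @export
flag_bradycardia <- function(rr, rr_threshold = 0.6, pair_sum = 1.2) {
  if (!inherits(rr, "interval_series"))
    crc_stop("crc_bad_argument", "'rr' must be an interval_series")
  v <- rr$values
  n <- length(v)
  if (n < 2L)
    crc_stop("crc_insufficient_data", "need >= 2 intervals to flag bradycardia")
  with_next <- c(v[-n] + v[-1], -Inf)   # v[k] + v[k+1], last has no successor
  with_prev <- c(-Inf, v[-n] + v[-1])   # v[k-1] + v[k], first has no predecessor
  flags <- (v >= rr_threshold) & (with_next >= pair_sum | with_prev >= pair_sum)
  structure(list(times = rr$times, values = v, flags = flags,
                 subject_id = rr$subject_id),
            class = "beat_flag_series")
}

#' Convert flagged beats into disjoint time spans
#'
#' Each maximal run of flagged intervals becomes one `[t_begin, t_end]` span:
#' from the start time of the first flagged interval (its end time minus its
#' value, by the end-anchoring convention) to the end time of the last. Runs
#' separated by unflagged intervals stay separate spans.
#'
#' @param bf a `beat_flag_series` from [flag_bradycardia()].
#' @return An object of class `span_set`: a data.frame with columns `begin`
#'   and `end` (seconds), disjoint and sorted; zero rows when nothing is
#'   flagged.
#' @export
flags_to_spans <- function(bf) {
  if (!inherits(bf, "beat_flag_series"))
    crc_stop("crc_bad_argument", "'bf' must be a beat_flag_series")
  r <- rle(bf$flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  begin <- bf$times[starts[keep]] - bf$values[starts[keep]]
  end <- bf$times[ends[keep]]
  span_set(begin, end)
}

#' Construct a span set
#' @param begin,end numeric vectors of span limits in seconds; must be
#'   pairwise `begin < end`, sorted and non-overlapping.
#' @return A data.frame of class `span_set`.
#' @export
span_set <- function(begin = numeric(0), end = numeric(0)) {
  if (length(begin) != length(end))
    crc_stop("crc_bad_argument", "begin and end must have equal length")
  if (any(begin >= end))
    crc_stop("crc_bad_argument", "every span must have begin < end")
  if (length(begin) > 1L) {
    o <- order(begin)
    begin <- begin[o]; end <- end[o]
    if (any(begin[-1] < end[-length(end)]))
      crc_stop("crc_bad_argument", "spans must be non-overlapping")
  }
  structure(data.frame(begin = begin, end = end),
            class = c("span_set", "data.frame"))
}

#' Label uniform-grid samples by span membership
#'
#' @param u a [uniform_series].
#' @param spans a [span_set] sharing the time origin of `u`.
#' @return Logical mask, one per grid sample: `TRUE` iff the grid time lies in
#'   some span, closed on the left and open on the right
#'   (`begin <= t < end`).
#' @export
label_grid <- function(u, spans) {
  if (!inherits(u, "uniform_series"))
    crc_stop("crc_bad_argument", "'u' must be a uniform_series")
  t <- grid_times(u)
  mask <- rep(FALSE, length(t))
  for (i in seq_len(nrow(spans)))
    mask <- mask | (t >= spans$begin[i] & t < spans$end[i])
  mask
}

#' Paired condition sample
#'
#' Equal-length paired R-R and IBI values for one condition (bradycardic `"B"`
#' or non-bradycardic `"NB"`), with the grid indices they came from so pairing
#' is traceable.
#'
#' @param condition `"B"` or `"NB"`.
#' @param rr,ibi paired value vectors (seconds), equal length.
#' @param indices grid indices of the samples.
#' @return An object of class `paired_condition_sample`.
#' @export
paired_condition_sample <- function(condition = c("B", "NB"), rr, ibi,
                                    indices = seq_along(rr)) {
  condition <- match.arg(condition)
  if (length(rr) != length(ibi) || length(rr) != length(indices))
    crc_stop("crc_pairing_error", "rr, ibi and indices must have equal length")
  structure(list(condition = condition, rr = as.numeric(rr),
                 ibi = as.numeric(ibi), indices = as.integer(indices)),
            class = "paired_condition_sample")
}

#' Split synchronous R-R / IBI grids into condition samples
#'
#' @param u_rr,u_ibi [uniform_series] on the identical grid (same `t0`, `fs`
#'   and length).
#' @param mask logical bradycardia mask from [label_grid()].
#' @return List with elements `b` and `nb`, each a
#'   [paired_condition_sample]; their index sets partition the grid.
#' @export
split_conditions <- function(u_rr, u_ibi, mask) {
  if (length(u_rr$values) != length(u_ibi$values) ||
      abs(u_rr$t0 - u_ibi$t0) > 1e-9 || u_rr$fs != u_ibi$fs)
    crc_stop("crc_pairing_error", "RR and IBI series must share the same grid")
  if (length(mask) != length(u_rr$values))
    crc_stop("crc_pairing_error", "mask length must match the grid")
  ib <- which(mask); inb <- which(!mask)
  list(b = paired_condition_sample("B", u_rr$values[ib], u_ibi$values[ib], ib),
       nb = paired_condition_sample("NB", u_rr$values[inb], u_ibi$values[inb], inb))
}

#' Balance conditions by random undersampling
#'
#' Draws, uniformly without replacement, a subset of the majority (NB) paired
#' samples of exactly the minority (B) sample count. Pairing is preserved: the
#' same grid index selects both the R-R and the IBI value. Draws come from R's
#' current random stream, so results are deterministic given a seed.
#'
#' @param b minority-condition [paired_condition_sample].
#' @param nb majority-condition [paired_condition_sample]; must be at least as
#'   long as `b`.
#' @param min_b_samples minimum usable minority size; fewer B samples raise a
#'   `crc_subject_excluded` error (default 8 grid samples = 2 s at 4 Hz).
#' @return The undersampled NB [paired_condition_sample], same length as `b`.
#' @export
balance_rus <- function(b, nb, min_b_samples = 8L) {
  if (!inherits(b, "paired_condition_sample") ||
      !inherits(nb, "paired_condition_sample"))
    crc_stop("crc_bad_argument", "'b' and 'nb' must be paired_condition_samples")
  n_b <- length(b$rr); n_nb <- length(nb$rr)
  if (n_b < min_b_samples)
    crc_stop("crc_subject_excluded",
             "only %d bradycardic grid samples (< %d): subject-trial unusable",
             n_b, min_b_samples)
  if (n_nb < n_b)
    crc_stop("crc_balance_error",
             "majority condition (%d) shorter than minority (%d)", n_nb, n_b)
  sel <- sort(sample.int(n_nb, n_b, replace = FALSE))
  paired_condition_sample("NB", nb$rr[sel], nb$ibi[sel], nb$indices[sel])
}
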