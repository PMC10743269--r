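#' Analysis parameters for the coupling pipeline
#'
#' Bundles every tunable of the per-trial pipeline: the preprocessing filter,
#' the resampling grid, the bradycardia rule and the histogram alphabet.
#'
#' @param filter a [filter_params] object.
#' @param fs resampling rate in Hz (default 4).
#' @param interp interpolation method for resampling, `"pchip"` or `"linear"`.
#' @param n_bins histogram bins per variable for the information measures
#'   (default 16; also the joint histogram is `n_bins x n_bins`).
#' @param min_b_samples minimum bradycardic grid samples for a subject-trial
#'   to be usable (default 8, i.e. 2 s at 4 Hz).
#' @param rr_threshold bradycardia R-R threshold in seconds (default 0.6,
#'   100 bpm).
#' @param pair_sum minimum two-beat span in seconds (default 1.2).
#' @return An object of class `crc_params`.
#' @export
crc_params <- function(filter = filter_params(), fs = 4,
                       interp = c("pchip", "linear"),
                       n_bins = 16L, min_b_samples = 8L,
                       rr_threshold = 0.6, pair_sum = 1.2) {
  interp <- match.arg(interp)
  if (!inherits(filter, "filter_params"))
    crc_stop("crc_bad_argument", "'filter' must be a filter_params object")
  stopifnot_scalar_num(fs, "fs", positive = TRUE)
  stopifnot_scalar_num(rr_threshold, "rr_threshold", positive = TRUE)
  stopifnot_scalar_num(pair_sum, "pair_sum", positive = TRUE)
  n_bins <- as.integer(n_bins)
  min_b_samples <- as.integer(min_b_samples)
  if (n_bins < 2L) crc_stop("crc_bad_argument", "'n_bins' must be >= 2")
  if (min_b_samples < 1L) crc_stop("crc_bad_argument", "'min_b_samples' must be >= 1")
  structure(list(filter = filter, fs = fs, interp = interp, n_bins = n_bins,
                 min_b_samples = min_b_samples, rr_threshold = rr_threshold,
                 pair_sum = pair_sum),
            class = "crc_params")
}
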