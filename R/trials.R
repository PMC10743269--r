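#' Prepare a subject for the trial protocol
#'
#' Derives the R-R and IBI interval series from the beat and breath event
#' series and removes recognition errors (zero-length intervals and pauses)
#' once; the stochastic steps (adaptive filtering, balancing) are repeated per
#' trial by [run_trial()].
#'
#' @param beats,breaths [event_series] of kinds `"beat"` and `"breath"`.
#' @param params a [crc_params] object.
#' @param subject_id subject label; defaults to the beat series' label.
#' @return An object of class `crc_subject`: list with `subject_id`, cleaned
#'   `rr` and `ibi` interval series.
#' @export
prepare_subject <- function(beats, breaths, params = crc_params(),
                            subject_id = NULL) {
  if (!inherits(beats, "event_series") || beats$kind != "beat")
    crc_stop("crc_bad_argument", "'beats' must be an event_series of kind 'beat'")
  if (!inherits(breaths, "event_series") || breaths$kind != "breath")
    crc_stop("crc_bad_argument", "'breaths' must be an event_series of kind 'breath'")
  if (is.null(subject_id)) subject_id <- beats$subject_id
  rr <- remove_recognition_errors(intervals_from_events(beats), params$filter)
  ibi <- remove_recognition_errors(intervals_from_events(breaths), params$filter)
  structure(list(subject_id = subject_id, rr = rr, ibi = ibi),
            class = "crc_subject")
}

#' Run one trial of the coupling pipeline for one subject
#'
#' Executes the stochastic portion of the pipeline under a trial seed:
#' adaptive filtering of both interval series, synchronous 4 Hz resampling on
#' the intersection of their time spans, bradycardia flagging on the filtered
#' beat-wise R-R series, span transfer to the grid, random undersampling of
#' the non-bradycardic majority, and the five information measures per
#' condition on the shared pooled binning.
#'
#' @param subject a [prepare_subject()] result.
#' @param params a [crc_params] object.
#' @param seed integer trial seed; the only source of randomness.
#' @return A data.frame with two rows (conditions `"B"` and `"NB"`) and
#'   columns `subject`, `condition`, `H_rr`, `H_ibi`, `MI`, `cH_rr_ibi`,
#'   `cH_ibi_rr` (all in bits).
#' @export
run_trial <- function(subject, params = crc_params(), seed = 1L) {
  if (!inherits(subject, "crc_subject"))
    crc_stop("crc_bad_argument", "'subject' must be a crc_subject")
  set.seed(as.integer(seed))
  rr_f <- adaptive_filter(subject$rr, params$filter)
  ibi_f <- adaptive_filter(subject$ibi, params$filter)
  t0 <- max(rr_f$times[1], ibi_f$times[1])
  t1 <- min(rr_f$times[length(rr_f$times)], ibi_f$times[length(ibi_f$times)])
  if (t1 - t0 < 4 / params$fs)
    crc_stop("crc_insufficient_data", "RR and IBI spans barely overlap")
  u_rr <- resample_uniform(rr_f, params$fs, t0, t1, params$interp)
  u_ibi <- resample_uniform(ibi_f, params$fs, t0, t1, params$interp)
  bf <- flag_bradycardia(rr_f, params$rr_threshold, params$pair_sum)
  spans <- flags_to_spans(bf)
  mask <- label_grid(u_rr, spans)
  cond <- split_conditions(u_rr, u_ibi, mask)
  nb_bal <- balance_rus(cond$b, cond$nb, params$min_b_samples)
  metrics <- condition_metrics(cond$b, nb_bal, params$n_bins)
  cbind(subject = subject$subject_id, metrics)
}

# five information measures for the two balanced conditions on shared binning
condition_metrics <- function(b, nb, n_bins) {
  spec <- make_binning(c(b$rr, nb$rr), c(b$ibi, nb$ibi), n_bins)
  one <- function(s) {
    p_rr <- hist_prob(s$rr, spec$edges_rr)
    p_ibi <- hist_prob(s$ibi, spec$edges_ibi)
    j <- joint_hist_prob(s$rr, s$ibi, spec)
    data.frame(condition = s$condition,
               H_rr = shannon_entropy(p_rr),
               H_ibi = shannon_entropy(p_ibi),
               MI = mutual_information(j),
               cH_rr_ibi = cross_entropy(p_rr, p_ibi),
               cH_ibi_rr = cross_entropy(p_ibi, p_rr))
  }
  rbind(one(b), one(nb))
}

crc_metric_names <- c("H_rr", "H_ibi", "MI", "cH_rr_ibi", "cH_ibi_rr")

#' Run the repeated-trial protocol for one subject
#'
#' Repeats [run_trial()] `n_trials` times with seeds `base_seed + k`
#' (`k = 1..n_trials`) and aggregates each metric, per condition, as the
#' median over completed trials. Trials failing for lack of bradycardic data
#' are recorded and skipped; a subject with zero completed trials raises a
#' `crc_subject_excluded` error.
#'
#' @param subject a [prepare_subject()] result.
#' @param n_trials number of trials (default 100).
#' @param base_seed integer; trial `k` uses seed `base_seed + k`.
#' @param params a [crc_params] object.
#' @return An object of class `crc_subject_trials`: list with `subject_id`,
#'   `trials` (per-trial metric rows), `summary` (two-row data.frame of
#'   per-condition medians), and counts of completed/failed trials.
#' @export
run_trials <- function(subject, n_trials = 100L, base_seed = 1L,
                       params = crc_params()) {
  n_trials <- as.integer(n_trials)
  if (n_trials < 1L) crc_stop("crc_bad_argument", "'n_trials' must be >= 1")
  rows <- vector("list", n_trials)
  failed <- 0L
  for (k in seq_len(n_trials)) {
    res <- tryCatch(
      cbind(trial = k, run_trial(subject, params, seed = base_seed + k)),
      crc_subject_excluded = function(e) NULL,
      crc_insufficient_data = function(e) NULL,
      crc_degenerate_data = function(e) NULL)
    if (is.null(res)) failed <- failed + 1L else rows[[k]] <- res
  }
  trials <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(trials) || nrow(trials) == 0L)
    crc_stop("crc_subject_excluded",
             "subject %s: no completed trials out of %d", subject$subject_id,
             n_trials)
  structure(list(subject_id = subject$subject_id,
                 trials = trials,
                 summary = summarize_trials(trials),
                 n_completed = n_trials - failed,
                 n_failed = failed),
            class = "crc_subject_trials")
}

#' Median aggregation of per-trial metrics
#'
#' Per condition, the median of each metric over the recorded trials.
#' Permutation-invariant over trial order.
#'
#' @param trials data.frame of trial rows as produced by [run_trial()] (any
#'   number of trials, both conditions).
#' @return Two-row data.frame (`condition`, metric medians, `n_trials`).
#' @export
summarize_trials <- function(trials) {
  out <- lapply(split(trials, trials$condition), function(d) {
    med <- vapply(crc_metric_names, function(m) stats::median(d[[m]]), numeric(1))
    cbind(data.frame(subject = d$subject[1], condition = d$condition[1]),
          as.data.frame(as.list(med)), n_trials = nrow(d))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare conditions across subjects
#'
#' For each of the five metrics, tests the per-subject medians of the
#' bradycardic condition against the non-bradycardic condition with the exact
#' Wilcoxon matched-pairs signed-rank test, and reports the cohort mean and
#' standard deviation per condition as descriptive output. A metric whose
#' differences are all zero is reported with `NA` statistics without aborting
#' the other metrics.
#'
#' @param summaries data.frame of per-subject condition medians: row-bound
#'   `summary` components of [run_trials()] results (or the `summaries` slot
#'   of a [crc_study] object).
#' @return A data.frame with one row per metric: `metric`, `mean_B`, `sd_B`,
#'   `mean_NB`, `sd_NB`, `W`, `p_value`.
#' @export
cohort_compare <- function(summaries) {
  subjects <- unique(summaries$subject)
  if (length(subjects) < 3L)
    crc_stop("crc_cohort_error", "need >= 3 subjects, got %d", length(subjects))
  b <- summaries[summaries$condition == "B", ]
  nb <- summaries[summaries$condition == "NB", ]
  b <- b[match(subjects, b$subject), ]
  nb <- nb[match(subjects, nb$subject), ]
  rows <- lapply(crc_metric_names, function(m) {
    x <- b[[m]]; y <- nb[[m]]
    ht <- tryCatch(wilcoxon_exact(x, y),
                   crc_degenerate_test = function(e) NULL)
    data.frame(metric = m,
               mean_B = mean(x), sd_B = stats::sd(x),
               mean_NB = mean(y), sd_NB = stats::sd(y),
               W = if (is.null(ht)) NA_real_ else unname(ht$statistic),
               p_value = if (is.null(ht)) NA_real_ else ht$p.value)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
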