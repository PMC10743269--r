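#' Configuration of the synthetic cardiorespiratory cohort generator
#'
#' Defines the statistical structure the generator emulates: neonatal heart
#' rates (per-subject mean R-R drawn from `mean_rr`), breath-to-breath
#' intervals around `mean_ibi` with AR(1) correlation, respiratory sinus
#' modulation of the R-R series with a tunable coupling depth (different
#' inside and outside bradycardia episodes), and injectable bradycardia
#' episodes in which the R-R interval is elongated past 0.6 s for several
#' beats with a ramped onset and offset.
#'
#' @param n_subjects number of subjects (default 10).
#' @param duration record length per subject, seconds (default 7200. Two
#'   hours yields enough bradycardia episodes, about 80 at the default rate,
#'   for stable bradycardic-condition histograms; with much shorter records
#'   the handful of serially correlated episode samples carries too few
#'   effective degrees of freedom for the plug-in estimators).
#' @param mean_rr mean R-R in seconds: a scalar, or a length-2 range from
#'   which each subject's mean is drawn uniformly. The default range
#'   0.36-0.42 s keeps per-subject mean heart rates within the 131-167 bpm
#'   band observed clinically while leaving headroom below the 0.6 s
#'   bradycardia threshold.
#' @param mean_ibi mean inter-breath interval, seconds (default 1.5, about 40
#'   breaths/min).
#' @param ibi_cv stationary coefficient of variation of the IBI process
#'   (default 0.2).
#' @param ibi_ar1 lag-1 autocorrelation of the IBI process (default 0.9:
#'   breath durations wander slowly with autonomic state rather than jumping
#'   independently breath to breath).
#' @param coupling_nb cardiorespiratory coupling depth `m` outside episodes,
#'   in `[0, 0.5]` (default 0.3). `m` scales both the phasic respiratory
#'   modulation of R-R and the co-variation of the R-R baseline with the
#'   current breath duration (see [generate_beats()]).
#' @param coupling_b coupling depth during episodes (default 0.05; episodes
#'   suppress coupling).
#' @param rsa_weight,tone_weight relative weights of the two coupling
#'   channels inside `m`: phase-locked respiratory modulation (`rsa_weight`,
#'   default 0.5) and shared-drive baseline co-variation with breath duration
#'   (`tone_weight`, default 1.5).
#' @param brady_rate bradycardia episodes per hour (default 40, within the
#'   event rates seen in symptomatic apnea of prematurity).
#' @param brady_depth multiplicative R-R elongation at the episode plateau
#'   (default 2.0, i.e. heart rate roughly halves; guarantees the plateau
#'   stays above 0.6 s under episode-level modulation).
#' @param brady_beats plateau length in beats (default 12, giving episodes
#'   roughly 10-15 s long including ramps, typical of apnea-associated
#'   bradycardia).
#' @param brady_depth_jitter optional fractional per-episode variation of
#'   the depth (each episode's elongation is scaled by a uniform draw from
#'   `[1 - jitter, 1 + jitter]`). Default 0: every episode reaches the same
#'   plateau, which keeps the bradycardic R-R distribution well defined.
#' @param brady_ramp onset/offset ramp length in beats (default 4); the
#'   elongation rises geometrically, mimicking a deceleration over several
#'   beats rather than a single-beat step.
#' @param rr_noise_cv multiplicative Gaussian beat-to-beat noise on R-R
#'   (default 0.03).
#' @param seed integer master seed; all cohort randomness derives from it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 10L, duration = 7200,
                         mean_rr = c(0.36, 0.42), mean_ibi = 1.5,
                         ibi_cv = 0.2, ibi_ar1 = 0.9,
                         coupling_nb = 0.3, coupling_b = 0.05,
                         rsa_weight = 0.5, tone_weight = 1.5,
                         brady_rate = 40, brady_depth = 2.0,
                         brady_beats = 12L, brady_ramp = 4L,
                         brady_depth_jitter = 0,
                         rr_noise_cv = 0.03, seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 1L) crc_stop("crc_bad_argument", "'n_subjects' must be >= 1")
  stopifnot_scalar_num(duration, "duration", positive = TRUE)
  if (!length(mean_rr) %in% c(1L, 2L) || any(mean_rr <= 0))
    crc_stop("crc_bad_argument", "'mean_rr' must be a positive scalar or range")
  stopifnot_scalar_num(mean_ibi, "mean_ibi", positive = TRUE)
  stopifnot_scalar_num(ibi_cv, "ibi_cv"); if (ibi_cv < 0)
    crc_stop("crc_bad_argument", "'ibi_cv' must be >= 0")
  stopifnot_scalar_num(ibi_ar1, "ibi_ar1")
  if (abs(ibi_ar1) >= 1) crc_stop("crc_bad_argument", "'ibi_ar1' must be in (-1, 1)")
  for (m in c(coupling_nb = coupling_nb, coupling_b = coupling_b))
    if (m < 0 || m > 0.5)
      crc_stop("crc_bad_argument", "coupling depths must lie in [0, 0.5]")
  stopifnot_scalar_num(rsa_weight, "rsa_weight")
  stopifnot_scalar_num(tone_weight, "tone_weight")
  if (rsa_weight < 0 || tone_weight < 0)
    crc_stop("crc_bad_argument", "coupling channel weights must be >= 0")
  stopifnot_scalar_num(brady_rate, "brady_rate"); if (brady_rate < 0)
    crc_stop("crc_bad_argument", "'brady_rate' must be >= 0")
  stopifnot_scalar_num(brady_depth, "brady_depth", positive = TRUE)
  if (brady_depth * max(mean_rr) < 0.6)
    crc_stop("crc_bad_argument",
             "brady_depth * mean_rr must reach 0.6 s so episodes are bradycardic")
  brady_beats <- as.integer(brady_beats); brady_ramp <- as.integer(brady_ramp)
  stopifnot_scalar_num(brady_depth_jitter, "brady_depth_jitter")
  if (brady_depth_jitter < 0 || brady_depth_jitter >= 1)
    crc_stop("crc_bad_argument", "'brady_depth_jitter' must be in [0, 1)")
  if (brady_beats < 2L) crc_stop("crc_bad_argument", "'brady_beats' must be >= 2")
  if (brady_ramp < 0L) crc_stop("crc_bad_argument", "'brady_ramp' must be >= 0")
  stopifnot_scalar_num(rr_noise_cv, "rr_noise_cv"); if (rr_noise_cv < 0)
    crc_stop("crc_bad_argument", "'rr_noise_cv' must be >= 0")
  structure(list(n_subjects = n_subjects, duration = duration,
                 mean_rr = mean_rr, mean_ibi = mean_ibi, ibi_cv = ibi_cv,
                 ibi_ar1 = ibi_ar1, coupling_nb = coupling_nb,
                 coupling_b = coupling_b, rsa_weight = rsa_weight,
                 tone_weight = tone_weight, brady_rate = brady_rate,
                 brady_depth = brady_depth, brady_beats = brady_beats,
                 brady_ramp = brady_ramp, brady_depth_jitter = brady_depth_jitter,
                 rr_noise_cv = rr_noise_cv,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a breath event series
#'
#' Breath-to-breath intervals follow a stationary AR(1) process around
#' `mean_ibi` with lag-1 correlation `ibi_ar1` and coefficient of variation
#' `ibi_cv`, truncated below at a quarter of the mean so intervals stay
#' positive. Cumulative sums give breath event times from 0 covering the
#' record duration. Uses R's current random stream.
#'
#' @param cfg a [synth_config].
#' @param subject_id label for the generated series.
#' @return An [event_series] of kind `"breath"`.
#' @export
generate_breaths <- function(cfg, subject_id = "synth") {
  n <- ceiling(cfg$duration / cfg$mean_ibi * 1.6) + 60L
  if (cfg$ibi_cv == 0) {
    iv <- rep(cfg$mean_ibi, n)
  } else {
    sd_st <- cfg$ibi_cv * cfg$mean_ibi
    innov <- stats::rnorm(n, 0, sd_st * sqrt(1 - cfg$ibi_ar1^2))
    dev <- as.numeric(stats::filter(innov, cfg$ibi_ar1, method = "recursive",
                                    init = stats::rnorm(1, 0, sd_st)))
    iv <- pmax(cfg$mean_ibi + dev, 0.25 * cfg$mean_ibi)
  }
  times <- c(0, cumsum(iv))
  last <- which(times >= cfg$duration)[1]
  if (is.na(last)) last <- length(times)
  event_series(times[seq_len(last)], "breath", subject_id)
}

#' Generate a beat event series coupled to a breath series
#'
#' Beats are generated sequentially. The next R-R interval is
#' \deqn{RR = \bar{RR} \cdot f \cdot (1 + m [a_{rsa} w \sin(2\pi\phi)
#'   + a_{tone} (w - 1)]) \cdot (1 + \epsilon)}
#' where `phi` is the fractional phase of the current breath cycle at the
#' beat time, `w` is the current breath's duration relative to `mean_ibi`
#' (clipped to `[0.6, 1.4]`), `m` is `coupling_b` inside an episode and
#' `coupling_nb` outside, `a_rsa = rsa_weight`, `a_tone = tone_weight`,
#' `eps` is Gaussian noise with sd `rr_noise_cv`, and `f` is the episode
#' elongation factor (1 outside episodes; a geometric ramp up to
#' `brady_depth`, a plateau of `brady_beats` beats, and a ramp down inside).
#'
#' The two channels inside `m` emulate the two faces of vagally mediated
#' cardiorespiratory coupling: phase-locked respiratory sinus modulation
#' (whose amplitude grows with breath duration), and a shared slow drive that
#' lengthens the heart period when breathing slows. The second channel is
#' what makes the instantaneous R-R value informative about the concurrent
#' IBI value -- the dependence that histogram-based (order-invariant) mutual
#' information measures; a phase-locked modulation of fixed amplitude alone
#' would leave the value-vs-value joint distribution essentially independent.
#'
#' Episode start times form a Poisson process with rate `brady_rate` per hour
#' (thinned to keep episodes separated). Ground truth is recorded from the
#' emitted intervals: each maximal run of two or more consecutive in-episode
#' intervals of at least 0.6 s becomes one truth span.
#'
#' @param breaths a breath [event_series] (from [generate_breaths()]).
#' @param cfg a [synth_config].
#' @param mean_rr this subject's mean R-R in seconds (scalar).
#' @param subject_id label for the generated series.
#' @return List with `beats` (an [event_series]), `truth_spans` (a
#'   [span_set]), and `n_episodes` (episodes injected).
#' @export
generate_beats <- function(breaths, cfg, mean_rr = mean(cfg$mean_rr),
                           subject_id = "synth") {
  bt <- breaths$times
  dur <- min(cfg$duration, bt[length(bt)])
  ramp <- cfg$brady_ramp
  prof <- c(cfg$brady_depth^(seq_len(ramp) / (ramp + 1)),
            rep(cfg$brady_depth, cfg$brady_beats),
            cfg$brady_depth^(rev(seq_len(ramp)) / (ramp + 1)))
  ep_len <- length(prof) * cfg$brady_depth * mean_rr
  starts <- numeric(0)
  if (cfg$brady_rate > 0) {
    n_ep <- stats::rpois(1, cfg$brady_rate * dur / 3600)
    if (n_ep > 0 && dur > 2 * (ep_len + 30)) {
      cand <- sort(stats::runif(n_ep, 30, dur - ep_len - 30))
      # keep episodes at least 20 s apart
      for (s in cand)
        if (length(starts) == 0 || s - starts[length(starts)] > ep_len + 20)
          starts <- c(starts, s)
    }
  }
  est_n <- ceiling(dur / (mean_rr * 0.8)) + 10L
  eps <- if (cfg$rr_noise_cv > 0) stats::rnorm(est_n, 0, cfg$rr_noise_cv)
         else numeric(est_n)
  t_out <- rr_out <- numeric(est_n)
  in_ep <- logical(est_n)
  nb <- length(bt)
  t <- 0; k <- 0L; bi <- 1L; ei <- 1L; ep_pos <- 0L; dj <- 1
  repeat {
    while (bi < nb && bt[bi + 1L] <= t) bi <- bi + 1L
    if (bi >= nb) break
    ibi_cur <- bt[bi + 1L] - bt[bi]
    phi <- (t - bt[bi]) / ibi_cur
    w <- min(max(ibi_cur / cfg$mean_ibi, 0.6), 1.4)
    if (ep_pos == 0L && ei <= length(starts) && t >= starts[ei]) {
      ep_pos <- 1L
      dj <- if (cfg$brady_depth_jitter > 0)
        stats::runif(1, 1 - cfg$brady_depth_jitter, 1 + cfg$brady_depth_jitter)
      else 1
    }
    if (ep_pos > 0L) {
      f <- 1 + (prof[ep_pos] - 1) * dj; m <- cfg$coupling_b; ep_now <- TRUE
      ep_pos <- ep_pos + 1L
      if (ep_pos > length(prof)) { ep_pos <- 0L; ei <- ei + 1L }
    } else {
      f <- 1; m <- cfg$coupling_nb; ep_now <- FALSE
    }
    k <- k + 1L
    mod <- m * (cfg$rsa_weight * w * sin(2 * pi * phi) +
                cfg$tone_weight * (w - 1))
    rr <- mean_rr * f * (1 + mod) * (1 + eps[k])
    rr <- max(rr, 0.15)
    t <- t + rr
    if (t > dur || k > est_n - 1L) break
    t_out[k] <- t; rr_out[k] <- rr; in_ep[k] <- ep_now
  }
  n <- if (t_out[k] == 0) k - 1L else k
  t_out <- t_out[seq_len(n)]; rr_out <- rr_out[seq_len(n)]
  in_ep <- in_ep[seq_len(n)]
  beats <- event_series(c(0, t_out), "beat", subject_id)
  elong <- in_ep & rr_out >= 0.6
  r <- rle(elong)
  re <- cumsum(r$lengths); rs <- re - r$lengths + 1L
  keep <- r$values & r$lengths >= 2L
  truth <- span_set(t_out[rs[keep]] - rr_out[rs[keep]], t_out[re[keep]])
  list(beats = beats, truth_spans = truth, n_episodes = length(starts))
}

#' Generate a synthetic cohort of coupled beat/breath recordings
#'
#' Draws per-subject parameters and event series under per-subject seeds
#' derived deterministically from `cfg$seed`, so the same configuration always
#' yields byte-identical fixtures. Optionally serialises each subject as plain
#' event-text files (one timestamp per line) plus a JSON manifest recording
#' every parameter and seed.
#'
#' @param cfg a [synth_config].
#' @param dir optional output directory; created if needed.
#' @return An object of class `crc_cohort`: a list of subject fixtures, each
#'   with `subject_id`, `beats`, `breaths`, `truth_spans`, `mean_rr`,
#'   `n_episodes` and `seed`. The configuration is attached as attribute
#'   `"config"`.
#' @examples
#' cohort <- generate_cohort(synth_config(n_subjects = 2, duration = 300))
#' length(cohort)
#' @export
generate_cohort <- function(cfg, dir = NULL) {
  if (!inherits(cfg, "synth_config"))
    crc_stop("crc_bad_argument", "'cfg' must be a synth_config")
  set.seed(cfg$seed)
  subj_seeds <- sample.int(.Machine$integer.max %/% 2L, cfg$n_subjects)
  mean_rrs <- if (length(cfg$mean_rr) == 2L)
    stats::runif(cfg$n_subjects, cfg$mean_rr[1], cfg$mean_rr[2])
  else rep(cfg$mean_rr, cfg$n_subjects)
  fixtures <- vector("list", cfg$n_subjects)
  for (i in seq_len(cfg$n_subjects)) {
    id <- sprintf("S%02d", i)
    set.seed(subj_seeds[i])
    breaths <- generate_breaths(cfg, id)
    gb <- generate_beats(breaths, cfg, mean_rrs[i], id)
    fixtures[[i]] <- list(subject_id = id, beats = gb$beats, breaths = breaths,
                          truth_spans = gb$truth_spans, mean_rr = mean_rrs[i],
                          n_episodes = gb$n_episodes, seed = subj_seeds[i])
  }
  cohort <- structure(fixtures, class = "crc_cohort")
  attr(cohort, "config") <- cfg
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.crc_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<crc_cohort> %d subjects, %.0f s each, coupling NB/B = %.2f/%.2f\n",
              length(x), cfg$duration, cfg$coupling_nb, cfg$coupling_b))
  invisible(x)
}

write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- attr(cohort, "config")
  manifest <- list(config = unclass(cfg), subjects = list())
  for (f in cohort) {
    wb <- file.path(dir, paste0(f$subject_id, "_beats.txt"))
    wr <- file.path(dir, paste0(f$subject_id, "_breaths.txt"))
    writeLines(c(sprintf("# synthetic beat event times (s), subject %s", f$subject_id),
                 sprintf("%.6f", f$beats$times)), wb)
    writeLines(c(sprintf("# synthetic breath event times (s), subject %s", f$subject_id),
                 sprintf("%.6f", f$breaths$times)), wr)
    utils::write.csv(as.data.frame(f$truth_spans),
                     file.path(dir, paste0(f$subject_id, "_spans.csv")),
                     row.names = FALSE)
    manifest$subjects[[f$subject_id]] <- list(
      seed = f$seed, mean_rr = f$mean_rr, n_episodes = f$n_episodes,
      n_beats = length(f$beats$times), n_breaths = length(f$breaths$times),
      beats_file = basename(wb), breaths_file = basename(wr))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
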