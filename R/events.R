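#' Event series: timestamps of heartbeats or breaths
#'
#' An `event_series` holds the event times (seconds from record start) of one
#' channel of a recording: ECG R-peaks (`kind = "beat"`) or breath events
#' (`kind = "breath"`). Times must be non-negative and strictly increasing.
#'
#' @param times numeric vector of event times in seconds, strictly increasing.
#' @param kind `"beat"` or `"breath"`.
#' @param subject_id subject label carried through the pipeline.
#' @return An object of class `event_series`: a list with elements `times`,
#'   `kind` and `subject_id`.
#' @examples
#' ev <- event_series(c(0, 0.4, 0.8, 1.2), "beat", "S01")
#' intervals_from_events(ev)
#' @export
event_series <- function(times, kind = c("beat", "breath"), subject_id = "") {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  if (length(times) < 2L)
    crc_stop("crc_insufficient_data",
             "need at least 2 events, got %d", length(times))
  if (anyNA(times) || any(times < 0))
    crc_stop("crc_bad_argument", "event times must be non-negative and non-missing")
  if (!is_strictly_increasing(times))
    crc_stop("crc_ordering_error", "event times must be strictly increasing")
  structure(list(times = times, kind = kind, subject_id = as.character(subject_id)),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %s events: n = %d, span %.1f-%.1f s%s\n",
              x$kind, length(x$times), x$times[1], x$times[length(x$times)],
              if (nzchar(x$subject_id)) paste0(" [", x$subject_id, "]") else ""))
  invisible(x)
}

#' Read beat or breath event annotations from a file
#'
#' Two plain-text dialects are supported. `"event_text"` is one timestamp per
#' line in seconds ('.' decimal separator); lines starting with `#` are
#' ignored. `"wfdb_annotation"` is the tabular text emitted by the WFDB `rdann`
#' tool (elapsed time, sample number, annotation symbol, ...); the elapsed-time
#' column may be plain seconds or `[HH:]MM:SS.sss`. All annotation symbols are
#' accepted as events: the annotations are taken as ground truth.
#'
#' Duplicate timestamps are collapsed to a single event with a warning.
#'
#' @param path path to the annotation file.
#' @param kind `"beat"` or `"breath"`.
#' @param format `"event_text"` (default) or `"wfdb_annotation"`.
#' @param subject_id subject label; defaults to the file name without extension.
#' @return An [event_series].
#' @examples
#' f <- tempfile()
#' writeLines(c("# beat times (s)", "0.0", "0.4", "0.8"), f)
#' read_events(f, "beat")
#' @export
read_events <- function(path, kind = c("beat", "breath"),
                        format = c("event_text", "wfdb_annotation"),
                        subject_id = NULL) {
  kind <- match.arg(kind)
  format <- match.arg(format)
  if (!file.exists(path))
    crc_stop("crc_format_error", "file not found: %s", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    crc_stop("crc_format_error", "no event records in %s", path)

  times <- switch(format,
    event_text = {
      t <- suppressWarnings(as.numeric(lines))
      if (anyNA(t))
        crc_stop("crc_format_error", "non-numeric line in event_text file %s", path)
      t
    },
    wfdb_annotation = {
      fields <- strsplit(lines, "[[:space:]]+")
      t <- vapply(fields, function(f) parse_elapsed_time(f[[1]]), numeric(1))
      if (anyNA(t))
        crc_stop("crc_format_error", "unparseable elapsed time in %s", path)
      t
    })

  if (anyDuplicated(times)) {
    n_dup <- sum(duplicated(times))
    times <- unique(times)
    crc_warn("crc_duplicate_events",
             "collapsed %d duplicate event timestamp(s) in %s", n_dup, path)
  }
  if (length(times) < 2L)
    crc_stop("crc_insufficient_data",
             "fewer than 2 events in %s", path)
  if (!is_strictly_increasing(times))
    crc_stop("crc_ordering_error", "event times in %s are not increasing", path)
  event_series(times, kind, subject_id)
}

# "SS.sss", "MM:SS.sss" or "HH:MM:SS.sss" -> seconds
parse_elapsed_time <- function(s) {
  parts <- strsplit(s, ":", fixed = TRUE)[[1]]
  vals <- suppressWarnings(as.numeric(parts))
  if (anyNA(vals) || length(vals) > 3L) return(NA_real_)
  sum(vals * 60^(rev(seq_along(vals)) - 1))
}

#' Interval series: R-R or inter-breath intervals
#'
#' An `interval_series` pairs each interval duration with the timestamp of the
#' event that ends it (end-anchoring). Built by [intervals_from_events()];
#' filtering steps alter `values` but keep `times`.
#'
#' @param times event times in seconds ending each interval, strictly increasing.
#' @param values interval durations in seconds, all positive.
#' @param kind `"RR"` or `"IBI"`.
#' @param subject_id subject label.
#' @return An object of class `interval_series`.
#' @export
interval_series <- function(times, values, kind = c("RR", "IBI"), subject_id = "") {
  kind <- match.arg(kind)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    crc_stop("crc_bad_argument", "times and values must have equal length")
  if (length(times) == 0L)
    crc_stop("crc_insufficient_data", "empty interval series")
  if (!is_strictly_increasing(times))
    crc_stop("crc_ordering_error", "interval times must be strictly increasing")
  structure(list(times = times, values = values, kind = kind,
                 subject_id = as.character(subject_id)),
            class = "interval_series")
}

#' @export
print.interval_series <- function(x, ...) {
  cat(sprintf("<interval_series> %s: n = %d, mean %.3f s, span %.1f-%.1f s\n",
              x$kind, length(x$values), mean(x$values),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Derive an interval series from an event series
#'
#' Successive differences of the event times; interval `k` is anchored to the
#' event that ends it, so `values[k] = times[k] - times[k-1]` of the events and
#' the interval's time stamp is `times[k]` (end-anchoring). Beat events yield an
#' R-R series, breath events an IBI series.
#'
#' @param events an [event_series] with at least 2 events.
#' @return An [interval_series] with `length(events$times) - 1` intervals.
#' @export
intervals_from_events <- function(events) {
  if (!inherits(events, "event_series"))
    crc_stop("crc_bad_argument", "'events' must be an event_series")
  t <- events$times
  interval_series(times = t[-1], values = diff(t),
                  kind = if (events$kind == "beat") "RR" else "IBI",
                  subject_id = events$subject_id)
}
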