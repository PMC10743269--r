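# Internal condition helpers. Every domain failure carries a subclass so callers
# (and the trial loop) can react to specific failure modes without string matching.

crc_stop <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "crc_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

crc_warn <- function(subclass, msg, ...) {
  warning(structure(
    class = c(subclass, "crc_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    crc_stop("crc_bad_argument", "'%s' must be a finite numeric scalar", name)
  if (positive && x <= 0)
    crc_stop("crc_bad_argument", "'%s' must be > 0", name)
  invisible(x)
}

is_strictly_increasing <- function(x) all(diff(x) > 0)

# base-2 entropy of a bare probability vector with the 0*log2(0) = 0 convention
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
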