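# Independent brute-force oracles. These deliberately use naive loops and a
# different code path from the package so that agreement is informative.

# bin assignment: left-closed, right-open, last bin closed
oracle_bin <- function(x, edges) {
  nb <- length(edges) - 1L
  for (b in seq_len(nb)) {
    hi <- edges[b + 1L]
    if (b < nb) { if (x >= edges[b] && x < hi) return(b) }
    else if (x >= edges[b] && x <= hi) return(b)
  }
  stop("value out of range")
}

oracle_counts <- function(values, edges) {
  counts <- rep(0L, length(edges) - 1L)
  for (x in values) {
    b <- oracle_bin(x, edges)
    counts[b] <- counts[b] + 1L
  }
  counts
}

oracle_entropy <- function(p) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi) / log(2)
  h
}

oracle_cross_entropy <- function(p_counts, q_counts) {
  p <- p_counts / sum(p_counts)
  q <- q_counts / sum(q_counts)
  smooth <- FALSE
  for (i in seq_along(p)) if (p[i] > 0 && q[i] == 0) smooth <- TRUE
  if (smooth) q <- (q_counts + 0.5) / (sum(q_counts) + 0.5 * length(q_counts))
  s <- 0
  for (i in seq_along(p)) if (p[i] > 0) s <- s - p[i] * log(q[i]) / log(2)
  s
}

oracle_joint_counts <- function(xs, ys, ex, ey) {
  m <- matrix(0L, length(ex) - 1L, length(ey) - 1L)
  for (k in seq_along(xs)) {
    i <- oracle_bin(xs[k], ex); j <- oracle_bin(ys[k], ey)
    m[i, j] <- m[i, j] + 1L
  }
  m
}

oracle_mi <- function(joint_counts) {
  p <- joint_counts / sum(joint_counts)
  px <- rowSums(p); py <- colSums(p)
  oracle_entropy(px) + oracle_entropy(py) - oracle_entropy(as.vector(p))
}

# literal 2^n sign-assignment enumeration for the signed-rank test
oracle_wilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  total <- sum(r)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_plus <- as.vector(signs %*% r)
  p <- mean(pmin(w_plus, total - w_plus) <= w_obs + 1e-9)
  list(W = w_obs, p = p)
}

# reference adaptive filter: plain streaming loop carrying the variance
oracle_adaptive_filter <- function(v, params) {
  n <- length(v)
  k0 <- min(20L, n)
  mu <- mean(v[seq_len(k0)]); s2 <- stats::var(v[seq_len(k0)])
  out <- v
  for (k in seq_len(n)) {
    pct <- k > 1 && abs(v[k] - v[k - 1]) > params$percent_limit * v[k - 1]
    ctl <- abs(v[k] - mu) > params$sigma_mult * sqrt(s2)
    if (pct || ctl) out[k] <- stats::runif(1, mu - 0.5 * sqrt(s2), mu + 0.5 * sqrt(s2))
    mu <- (1 - params$adapt_coeff) * mu + params$adapt_coeff * v[k]
    s2 <- (1 - params$adapt_coeff) * s2 + params$adapt_coeff * (v[k] - mu)^2
  }
  out
}

# small synthetic configuration for fast module tests
small_cfg <- function(...) {
  synth_config(n_subjects = 3, duration = 900, seed = 42, ...)
}
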