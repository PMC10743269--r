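test_that("binning spans the pooled range with equal-width edges", {
  spec <- make_binning(c(0.3, 0.7, 0.5), c(1, 2), n_bins = 4)
  expect_equal(spec$edges_rr, c(0.3, 0.4, 0.5, 0.6, 0.7))
  expect_equal(spec$edges_ibi, seq(1, 2, by = 0.25))
  # shared alphabet: B and NB on disjoint sub-ranges still share edges
  spec2 <- make_binning(c(seq(0.6, 0.9, 0.1), seq(0.3, 0.5, 0.1)), c(1, 2), 6)
  expect_equal(range(spec2$edges_rr), c(0.3, 0.9))
  expect_error(make_binning(rep(0.4, 5), c(1, 2), 4), class = "crc_degenerate_data")
})

test_that("histogram probabilities count with right-open bins, last bin closed", {
  edges <- seq(0.3, 0.7, by = 0.1)
  d <- hist_prob(c(0.35, 0.45, 0.45, 0.65), edges)
  expect_equal(d$p, c(0.25, 0.5, 0, 0.25))
  expect_equal(d$n_samples, 4)
  expect_equal(sum(d$p), 1, tolerance = 1e-12)
  # a single value gives a delta distribution
  expect_equal(sort(hist_prob(0.55, edges)$p, decreasing = TRUE)[1], 1)
  # value exactly at the last edge falls in the last bin
  expect_equal(hist_prob(0.7, edges)$p, c(0, 0, 0, 1))
  # boundary between bins belongs to the right-hand bin
  expect_equal(hist_prob(0.4, edges)$p, c(0, 1, 0, 0))
  expect_error(hist_prob(0.75, edges), class = "crc_out_of_range")
})

test_that("entropy matches closed forms", {
  expect_identical(shannon_entropy(prob_dist(rep(1, 8))), 3)
  expect_identical(shannon_entropy(prob_dist(c(0, 5, 0))), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
})

test_that("cross-entropy follows the by-index definition with lazy smoothing", {
  u <- prob_dist(rep(2, 8))
  expect_equal(cross_entropy(u, u), 3)
  # p = [1, 0] from one sample against q from counts [1, 1]
  expect_equal(cross_entropy(prob_dist(c(1, 0)), prob_dist(c(1, 1))), 1.0)
  # frozen direct evaluation: -(0.75 log2 0.25 + 0.25 log2 0.75)
  expect_equal(cross_entropy(prob_dist(c(3, 1)), prob_dist(c(1, 3))),
               1.6037594, tolerance = 1e-6)
  # smoothing triggers only when q has an empty bin where p has mass
  p <- prob_dist(c(2, 2)); q0 <- prob_dist(c(4, 0))
  ch <- cross_entropy(p, q0)
  expect_true(is.finite(ch))
  qs <- c(4.5, 0.5) / 5
  expect_equal(ch, -sum(p$p * log2(qs)), tolerance = 1e-12)
  # no smoothing when p is zero exactly where q is empty
  expect_equal(cross_entropy(prob_dist(c(1, 0)), prob_dist(c(7, 0))), 0)
  expect_error(cross_entropy(prob_dist(c(1, 1)), prob_dist(c(1, 1, 1))),
               class = "crc_alphabet_error")
})

test_that("cross-entropy of a distribution with itself recovers its entropy", {
  set.seed(4)
  for (r in 1:20) {
    counts <- rpois(sample(2:6, 1), 4) + 1 # no empty bins
    d <- prob_dist(counts)
    expect_equal(cross_entropy(d, d), shannon_entropy(d), tolerance = 1e-12)
  }
})

test_that("joint histogram marginals are conserved", {
  spec <- make_binning(c(0.3, 0.9), c(1, 3), n_bins = 2)
  j <- joint_hist_prob(c(0.3, 0.3, 0.9, 0.9), c(1, 1, 3, 3), spec)
  expect_equal(j$p_xy, matrix(c(0.5, 0, 0, 0.5), 2))
  set.seed(9)
  rrv <- runif(40, 0.3, 0.9); ibv <- runif(40, 1, 3)
  spec2 <- make_binning(rrv, ibv, 5)
  j2 <- joint_hist_prob(rrv, ibv, spec2)
  expect_equal(rowSums(j2$p_xy), hist_prob(rrv, spec2$edges_rr)$p, tolerance = 1e-12)
  expect_equal(colSums(j2$p_xy), hist_prob(ibv, spec2$edges_ibi)$p, tolerance = 1e-12)
  expect_error(joint_hist_prob(1:3, 1:4, spec), class = "crc_pairing_error")
})

test_that("mutual information matches closed forms and frozen evaluations", {
  # independent joint: outer product of marginals
  px <- c(0.2, 0.3, 0.5); py <- c(0.6, 0.4)
  j <- structure(list(p_xy = outer(px, py), counts = NULL, n_samples = 100),
                 class = "joint_prob_dist")
  expect_equal(mutual_information(j), 0, tolerance = 1e-12)
  # perfectly dependent diagonal over 4 bins
  jd <- structure(list(p_xy = diag(4) / 4, counts = NULL, n_samples = 4),
                  class = "joint_prob_dist")
  expect_equal(mutual_information(jd), 2)
  # frozen direct evaluation of H(X) + H(Y) - H(X, Y)
  jm <- structure(list(p_xy = matrix(c(0.4, 0.1, 0.1, 0.4), 2), counts = NULL,
                       n_samples = 10), class = "joint_prob_dist")
  expect_equal(mutual_information(jm), 0.2780719, tolerance = 1e-6)
})

test_that("mutual information is symmetric and bounded by marginal entropies", {
  set.seed(12)
  for (r in 1:25) {
    n <- sample(5:40, 1)
    rrv <- runif(n, 0.3, 0.9); ibv <- runif(n, 1, 3)
    spec <- make_binning(rrv, ibv, sample(2:6, 1))
    j <- joint_hist_prob(rrv, ibv, spec)
    jt <- j; jt$p_xy <- t(j$p_xy)
    mi <- mutual_information(j)
    expect_lt(abs(mi - mutual_information(jt)), 1e-12)
    expect_gte(mi, -1e-12)
    expect_lte(mi, min(shannon_entropy(prob_dist(rowSums(j$counts))),
                       shannon_entropy(prob_dist(colSums(j$counts)))) + 1e-12)
  }
})

test_that("Gibbs inequality holds without smoothing", {
  set.seed(31)
  for (r in 1:50) {
    nb <- sample(2:6, 1)
    p <- prob_dist(rpois(nb, 3) + 1)
    q <- prob_dist(rpois(nb, 3) + 1)
    expect_gte(cross_entropy(p, q), shannon_entropy(p) - 1e-12)
  }
})

test_that("merging adjacent bins never increases entropy", {
  set.seed(17)
  for (r in 1:50) {
    nb <- sample(3:8, 1)
    counts <- rpois(nb, 2)
    counts[1] <- counts[1] + 1 # non-empty total
    p <- prob_dist(counts)
    k <- sample(nb - 1, 1)
    merged <- counts
    merged[k] <- merged[k] + merged[k + 1]
    pm <- prob_dist(merged[-(k + 1)])
    expect_lte(shannon_entropy(pm), shannon_entropy(p) + 1e-12)
  }
})

test_that("all four measures agree with the direct-summation oracle", {
  set.seed(77)
  for (r in 1:200) {
    nb <- sample(2:5, 1)
    n <- sample(2:20, 1)
    rrv <- runif(n, 0.3, 0.9); ibv <- runif(n, 1, 3)
    if (diff(range(rrv)) == 0 || diff(range(ibv)) == 0) next
    spec <- make_binning(rrv, ibv, nb)
    p_rr <- hist_prob(rrv, spec$edges_rr)
    p_ibi <- hist_prob(ibv, spec$edges_ibi)
    expect_equal(p_rr$counts, as.numeric(oracle_counts(rrv, spec$edges_rr)))
    expect_equal(shannon_entropy(p_rr), oracle_entropy(p_rr$p), tolerance = 1e-12)
    expect_equal(cross_entropy(p_rr, p_ibi),
                 oracle_cross_entropy(p_rr$counts, p_ibi$counts), tolerance = 1e-12)
    j <- joint_hist_prob(rrv, ibv, spec)
    jc <- oracle_joint_counts(rrv, ibv, spec$edges_rr, spec$edges_ibi)
    expect_equal(j$counts, matrix(as.numeric(jc), nrow(jc)))
    expect_lt(abs(mutual_information(j) - oracle_mi(jc)), 1e-12)
  }
})
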