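rr_series <- function(values) {
  interval_series(cumsum(values), values, "RR")
}

test_that("bradycardia rule flags sustained slow beats only", {
  expect_equal(flag_bradycardia(rr_series(c(0.5, 0.7, 0.7, 0.5)))$flags,
               c(FALSE, TRUE, TRUE, FALSE))
  # 0.65 + 0.50 = 1.15 < 1.2: one slow beat alone is not an episode
  expect_equal(flag_bradycardia(rr_series(c(0.65, 0.50, 0.40)))$flags,
               rep(FALSE, 3))
  # 0.59 fails the amplitude clause even though the pair sum reaches 1.2
  expect_equal(flag_bradycardia(rr_series(c(0.59, 0.61, 0.61)))$flags,
               c(FALSE, TRUE, TRUE))
  # terminal bradycardic interval pairs with its predecessor
  expect_equal(flag_bradycardia(rr_series(c(0.4, 0.7, 0.7)))$flags,
               c(FALSE, TRUE, TRUE))
  expect_error(flag_bradycardia(rr_series(0.7)), class = "crc_insufficient_data")
})

test_that("no interval below the amplitude threshold is ever flagged", {
  set.seed(21)
  for (r in 1:300) {
    v <- runif(sample(2:30, 1), 0.2, 1.0)
    bf <- flag_bradycardia(rr_series(v))
    expect_true(all(bf$values[bf$flags] >= 0.6))
  }
})

test_that("flag runs become disjoint spans anchored at interval starts", {
  bf <- structure(list(times = c(0.5, 1.2, 1.9, 2.4),
                       values = c(0.5, 0.7, 0.7, 0.5),
                       flags = c(FALSE, TRUE, TRUE, FALSE), subject_id = ""),
                  class = "beat_flag_series")
  sp <- flags_to_spans(bf)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$begin, 0.5)
  expect_equal(sp$end, 1.9)

  bf$flags <- rep(FALSE, 4)
  expect_equal(nrow(flags_to_spans(bf)), 0L)

  bf$flags <- rep(TRUE, 4)
  sp_all <- flags_to_spans(bf)
  expect_equal(nrow(sp_all), 1L)
  expect_equal(sp_all$begin, 0.0)
  expect_equal(sp_all$end, 2.4)

  bf$flags <- c(TRUE, FALSE, TRUE, FALSE) # separated runs stay separate
  expect_equal(nrow(flags_to_spans(bf)), 2L)
})

test_that("grid labeling is closed on the left and open on the right", {
  u <- uniform_series(rep(0.4, 41), fs = 4, t0 = 0, kind = "RR")
  mask <- label_grid(u, span_set(0.5, 1.9))
  marked <- grid_times(u)[mask]
  expect_equal(marked, seq(0.5, 1.75, by = 0.25))
  expect_false(mask[grid_times(u) == 2.0])
  expect_false(any(label_grid(u, span_set())))
  expect_true(all(label_grid(u, span_set(-1, 100))))
})

test_that("condition split partitions the grid and keeps pairing", {
  set.seed(3)
  n <- 100
  u_rr <- uniform_series(runif(n, 0.3, 0.5), 4, 0, "RR")
  u_ibi <- uniform_series(runif(n, 1, 2), 4, 0, "IBI")
  mask <- seq_len(n) %in% sample(n, 30)
  cond <- split_conditions(u_rr, u_ibi, mask)
  expect_setequal(c(cond$b$indices, cond$nb$indices), seq_len(n))
  expect_length(intersect(cond$b$indices, cond$nb$indices), 0)
  expect_equal(cond$b$rr, u_rr$values[cond$b$indices])
  expect_equal(cond$b$ibi, u_ibi$values[cond$b$indices])
})

test_that("random undersampling balances lengths and preserves pairing", {
  set.seed(14)
  b <- paired_condition_sample("B", runif(50, 0.6, 0.9), runif(50, 1, 2), 1:50)
  nb <- paired_condition_sample("NB", runif(5000, 0.3, 0.5), runif(5000, 1, 2), 51:5050)
  set.seed(7); sel1 <- balance_rus(b, nb)
  expect_length(sel1$rr, 50L)
  set.seed(7); sel2 <- balance_rus(b, nb)
  expect_identical(sel1, sel2)
  # pairing: selected rr/ibi come from the same original index
  pos <- match(sel1$indices, nb$indices)
  expect_equal(sel1$rr, nb$rr[pos])
  expect_equal(sel1$ibi, nb$ibi[pos])

  small_b <- paired_condition_sample("B", runif(3, 0.6, 0.9), runif(3, 1, 2), 1:3)
  expect_error(balance_rus(small_b, nb), class = "crc_subject_excluded")
  short_nb <- paired_condition_sample("NB", runif(10, 0.3, 0.5), runif(10, 1, 2), 1:10)
  expect_error(balance_rus(b, short_nb), class = "crc_balance_error")
})

test_that("undersampling selection is uniform over majority indices", {
  b <- paired_condition_sample("B", rep(0.7, 3), rep(1.5, 3), 1:3)
  nb <- paired_condition_sample("NB", rep(0.4, 10), rep(1.5, 10), 1:10)
  set.seed(2024)
  counts <- rep(0, 10)
  for (r in 1:5000) {
    sel <- balance_rus(b, nb, min_b_samples = 1L)
    counts[sel$indices] <- counts[sel$indices] + 1
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("hand-built step episode is segmented exactly", {
  v <- c(rep(0.45, 20), rep(0.7, 5), rep(0.45, 20))
  rr <- rr_series(v)
  bf <- flag_bradycardia(rr)
  expect_equal(which(bf$flags), 21:25)
  sp <- flags_to_spans(bf)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$begin, sum(v[1:20]), tolerance = 1e-12)
  expect_equal(sp$end, sum(v[1:25]), tolerance = 1e-12)
})
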