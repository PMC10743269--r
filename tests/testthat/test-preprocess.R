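test_that("recognition-error removal deletes zero-length and implausible intervals", {
  p <- filter_params()
  s <- interval_series(c(1, 2, 3), c(0.40, 1e-9, 0.42), "RR")
  expect_warning(out <- remove_recognition_errors(s, p),
                 class = "crc_quality_warning") # 1/3 removed > 20%
  expect_equal(out$values, c(0.40, 0.42))
  expect_identical(attr(out, "n_removed"), 1L)

  s2 <- interval_series(1:5, c(0.40, 3.5, 0.42, 0.41, 0.39), "RR")
  out2 <- remove_recognition_errors(s2, p)
  expect_equal(out2$values, c(0.40, 0.42, 0.41, 0.39))

  clean <- interval_series(1:10, runif(10, 0.3, 0.5), "RR")
  expect_identical(remove_recognition_errors(clean, p)$values, clean$values)

  all_bad <- interval_series(1:3, c(5, 6, 7), "RR")
  expect_error(suppressWarnings(remove_recognition_errors(all_bad, p)),
               class = "crc_insufficient_data")
})

test_that("IBI series use their own plausibility bounds", {
  p <- filter_params()
  s <- interval_series(1:4, c(2.5, 14.0, 20.0, 3.0), "IBI")
  expect_warning(out <- remove_recognition_errors(s, p),
                 class = "crc_quality_warning")
  expect_equal(out$values, c(2.5, 14.0, 3.0))
})

test_that("adaptive filter is the identity on outlier-free data for every seed", {
  s <- interval_series(1:100, rep(0.4, 100), "RR")
  for (seed in 1:3) {
    set.seed(seed)
    out <- adaptive_filter(s)
    expect_identical(out$values, s$values)
    expect_identical(nrow(attr(out, "replacements")), 0L)
  }
  expect_error(adaptive_filter(interval_series(1:5, rep(0.4, 5), "RR")),
               class = "crc_insufficient_data")
})

test_that("isolated spikes are replaced by draws from the adaptive band", {
  s <- interval_series(1:101, c(rep(0.4, 50), 1.2, rep(0.4, 50)), "RR")
  set.seed(1)
  out <- adaptive_filter(s, filter_params(percent_limit = 0.1))
  reps <- attr(out, "replacements")
  expect_true(51 %in% reps$index)
  # replacement contract: every replacement inside [mu_a - sigma_a/2, mu_a + sigma_a/2]
  expect_true(all(reps$replacement >= reps$mu_a - 0.5 * reps$sigma_a - 1e-12))
  expect_true(all(reps$replacement <= reps$mu_a + 0.5 * reps$sigma_a + 1e-12))
  # non-replaced samples untouched
  expect_identical(out$values[-reps$index], s$values[-reps$index])
})

test_that("different seeds change only the replaced positions", {
  set.seed(99)
  v <- runif(200, 0.38, 0.42)
  v[c(60, 120)] <- c(1.5, 0.9)
  s <- interval_series(1:200, v, "RR")
  set.seed(1); a <- adaptive_filter(s)
  set.seed(2); b <- adaptive_filter(s)
  ra <- attr(a, "replacements"); rb <- attr(b, "replacements")
  expect_identical(ra$index, rb$index)
  expect_gt(nrow(ra), 0)
  expect_identical(a$values[-ra$index], b$values[-ra$index])
  expect_true(all(a$values[ra$index] != b$values[ra$index]))
})

test_that("vectorised filter matches a streaming reference implementation", {
  p <- filter_params()
  for (r in 1:10) {
    set.seed(r)
    v <- runif(300, 0.3, 0.5)
    v[sample(300, 4)] <- c(1.4, 0.05, 2.2, 1.1)
    s <- interval_series(1:300, v, "RR")
    set.seed(1000 + r); a <- adaptive_filter(s, p)$values
    set.seed(1000 + r); b <- oracle_adaptive_filter(v, p)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("uniform resampling reproduces constants and linear ramps", {
  s <- interval_series(seq(0, 10, by = 0.5), rep(0.5, 21), "RR")
  u <- resample_uniform(s, fs = 4, t_start = 0, t_end = 10)
  expect_length(u$values, 41L) # floor(10 * 4) + 1
  expect_equal(u$values, rep(0.5, 41))
  expect_equal(grid_times(u), seq(0, 10, by = 0.25))

  set.seed(5)
  times <- sort(runif(60, 0, 20))
  times <- times[c(TRUE, diff(times) > 1e-3)]
  ramp <- interval_series(times, 0.4 + 0.01 * times, "RR")
  ur <- resample_uniform(ramp, fs = 4, t_start = min(times), t_end = max(times))
  expect_equal(ur$values, 0.4 + 0.01 * grid_times(ur), tolerance = 1e-6)

  expect_error(resample_uniform(s, fs = 4, t_start = -1, t_end = 10),
               class = "crc_extrapolation_error")
  expect_error(resample_uniform(s, fs = 4, t_start = 0, t_end = 11),
               class = "crc_extrapolation_error")
})

test_that("paired RR and IBI resampling share an identical grid", {
  set.seed(8)
  rr <- interval_series(cumsum(runif(80, 0.3, 0.5)), runif(80, 0.3, 0.5), "RR")
  ibi <- interval_series(cumsum(runif(25, 1, 2)), runif(25, 1, 2), "IBI")
  t0 <- max(rr$times[1], ibi$times[1])
  t1 <- min(max(rr$times), max(ibi$times))
  u1 <- resample_uniform(rr, 4, t0, t1)
  u2 <- resample_uniform(ibi, 4, t0, t1)
  expect_identical(u1$t0, u2$t0)
  expect_identical(u1$fs, u2$fs)
  expect_identical(length(u1$values), length(u2$values))
})

test_that("shape-preserving interpolation does not overshoot bradycardia steps", {
  v <- c(rep(0.4, 10), rep(0.8, 5), rep(0.4, 10))
  s <- interval_series(cumsum(v), v, "RR")
  u <- resample_uniform(s, fs = 4)
  expect_true(all(u$values >= min(v) - 1e-12))
  expect_true(all(u$values <= max(v) + 1e-12))
})
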