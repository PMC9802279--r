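test_that("window grid has 101 samples and boundary onsets are excluded", {
  x <- matrix(seq(0, 1, length.out = 150), 1, dimnames = list("N1", NULL))
  tr <- as_activity(x)                        # 30 s at 5/s
  mat <- align_to_events(tr, "N1", onsets = c(10, 3), window = c(-7, 13))
  expect_equal(ncol(mat$rows), 101L)          # 20 s * 5/s + 1
  expect_equal(nrow(mat$rows), 1L)            # onset 3 s: window starts < 0
  expect_equal(mat$n_excluded, 1L)
  expect_equal(mat$times[1], -7)
  expect_equal(mat$times[101], 13)
  expect_error(align_to_events(tr, "N1", onsets = 2), "no event instance")
  expect_error(align_to_events(tr, "missing", onsets = 10), "unknown neuron")
})

test_that("constant traces align to constant rows", {
  tr <- as_activity(matrix(3, 1, 200, dimnames = list("N1", NULL)))
  mat <- align_to_events(tr, "N1", onsets = c(10, 15, 20))
  expect_true(all(mat$rows == 3))
  expect_equal(nrow(mat$rows), 3L)
})

test_that("average_response normalizes to [0, 1] and flags constants", {
  flat <- as_aligned(rbind(rep(0, 101), rep(2, 101)))
  expect_warning(rc <- average_response(flat), "constant")
  expect_true(rc$constant)
  expect_true(all(rc$curve == 0))
  expect_equal(rc$n_instances, 2L)

  set.seed(1)
  bump <- as_aligned(t(replicate(6, dnorm(seq(-35, 65) / 5, 2, 1) + rnorm(101, 0, 0.01))))
  rc2 <- average_response(bump)
  expect_equal(min(rc2$curve), 0)
  expect_equal(max(rc2$curve), 1)
  expect_false(rc2$constant)

  ## affine invariance: gain scaling does not change the normalized curve
  kern <- dnorm(seq(-7, 13, 0.2), 1.2, 0.8)
  m1 <- as_aligned(rbind(kern, kern))
  m2 <- as_aligned(rbind(5 * kern + 3, 5 * kern + 3))
  expect_equal(average_response(m1)$curve, average_response(m2)$curve,
               tolerance = 1e-12)
})

test_that("average_response pools instances across animals", {
  kern <- dnorm(seq(-7, 13, 0.2), 1, 1)
  a1 <- as_aligned(rbind(kern, kern + 0.1))
  a2 <- as_aligned(matrix(2 * kern, 1, 101))
  rc <- average_response(list(a1, a2))
  expect_equal(rc$n_instances, 3L)
  expect_equal(rc$n_animals, 2L)
})

## a 60 s recording with one backward-slide interval, used to exercise the
## lag machinery with exactly known behavior rows
lag_fixture <- function(shift_samples = 0, negate = FALSE) {
  rate <- 5
  n <- 300
  e <- ethogram(data.frame(event_type = "backward_slide",
                           onset_s = 30, offset_s = 36),
                duration_s = 60)
  b <- numeric(n)
  tt <- (0:(n - 1)) / rate
  b[tt >= 30 & tt < 36] <- 1
  a <- if (shift_samples >= 0) c(rep(0, shift_samples), b)[1:n]
  else c(b[(1 - shift_samples):n], rep(0, -shift_samples))
  if (negate) a <- -a
  tr <- as_activity(matrix(a, 1, dimnames = list("N1", NULL)))
  mat <- align_to_events(tr, "N1", onsets = 30)
  lag_correlation(mat, e, "backward_slide")
}

test_that("activity equal to the behavior row correlates 1 at lag 0", {
  lc <- lag_fixture(0)
  expect_equal(lc$lag_samples, 0L)
  expect_equal(lc$mean_r, 1)
  expect_equal(nrow(lc$lag_table), 11L)   # exhaustive over the 11 lags
})

test_that("activity delayed by one sample selects lag +1 (exhaustive check)", {
  lc <- lag_fixture(1)
  expect_equal(lc$lag_samples, 1L)        # positive = activity follows behavior
  expect_equal(abs(lc$mean_r), 1)
  lc2 <- lag_fixture(-2)
  expect_equal(lc2$lag_samples, -2L)
})

test_that("anticorrelated activity gives mean r = -1 and one-sided p near 1", {
  lc <- lag_fixture(0, negate = TRUE)
  expect_equal(lc$lag_samples, 0L)
  expect_equal(lc$mean_r, -1)
  ## single instance: t undefined; construct a multi-instance anticorrelated case
  e <- ethogram(data.frame(event_type = rep("backward_slide", 3),
                           onset_s = c(30, 90, 150), offset_s = c(36, 96, 156)),
                duration_s = 200)
  rate <- 5; n <- 1000; tt <- (0:(n - 1)) / rate
  b <- numeric(n)
  for (i in 1:3) b[tt >= c(30, 90, 150)[i] & tt < c(36, 96, 156)[i]] <- 1
  set.seed(2)
  tr <- as_activity(matrix(-b + rnorm(n, 0, 0.01), 1,
                           dimnames = list("N1", NULL)))
  mat <- align_to_events(tr, "N1", onsets = c(30, 90, 150))
  lc3 <- lag_correlation(mat, e, "backward_slide")
  expect_lt(lc3$mean_r, -0.9)
  expect_gt(lc3$p_value, 0.99)
})

test_that("correlations stay in [-1, 1] and constant behavior rows drop", {
  set.seed(3)
  e <- ethogram(data.frame(event_type = "backward_slide",
                           onset_s = 100, offset_s = 110),
                duration_s = 300)
  tr <- as_activity(matrix(rnorm(1500), 1, dimnames = list("N1", NULL)))
  ## onset at 50 s: window [43, 63] contains no slide -> behavior constant
  mat <- align_to_events(tr, "N1", onsets = c(100, 50))
  lc <- lag_correlation(mat, e, "backward_slide")
  expect_equal(lc$n_dropped, 1L)
  expect_true(all(abs(lc$correlations) <= 1))
  expect_true(all(abs(lc$lag_table$mean_r) <= 1, na.rm = TRUE))
  mat2 <- align_to_events(tr, "N1", onsets = 50)
  expect_error(lag_correlation(mat2, e, "backward_slide"), "constant")
})

test_that("point-motif behavior rows are single-sample impulses", {
  e <- ethogram(data.frame(event_type = "turn_success", onset_s = 40,
                           offset_s = NA_real_),
                duration_s = 100)
  rate <- 5; n <- 500; tt <- (0:(n - 1)) / rate
  a <- numeric(n); a[tt == 40] <- 1   # impulse exactly at the onset sample
  tr <- as_activity(matrix(a, 1, dimnames = list("N1", NULL)))
  mat <- align_to_events(tr, "N1", onsets = 40)
  lc <- lag_correlation(mat, e, "turn_success")
  expect_equal(lc$lag_samples, 0L)
  expect_equal(lc$mean_r, 1)
})

test_that("peak latency uses earliest-maximum tie-breaking and the median", {
  tg <- seq(-35, 65) / 5
  row_peak <- function(at) as.numeric(abs(tg - at) < 1e-9)
  mat <- as_aligned(rbind(row_peak(1.2), row_peak(1.2), row_peak(1.2)))
  lat <- peak_latency(mat)
  expect_equal(lat$median_s, 1.2)
  expect_equal(lat$n, 3L)

  const <- as_aligned(matrix(1, 2, 101))
  lat2 <- peak_latency(const, search = c(-2, 5))
  expect_equal(lat2$peak_times_s, c(-2, -2))   # tie -> earliest sample
  expect_equal(lat2$constant_rows, 2L)

  ## search range restriction
  two_peaks <- as_aligned(matrix(row_peak(-3) * 2 + row_peak(4), 1, 101))
  expect_equal(peak_latency(two_peaks)$median_s, -3)
  expect_equal(peak_latency(two_peaks, search = c(0, 13))$median_s, 4)
})

test_that("compare_latencies is the exact rank-sum on small groups", {
  mk <- function(v, g) structure(list(peak_times_s = v, median_s = median(v),
                                      n = length(v), group = g,
                                      constant_rows = 0L),
                                 class = "latency_summary")
  res <- compare_latencies(mk(c(1, 2, 3), "succ"), mk(c(101, 102, 103), "fail"))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, ranksum_exact_p(c(1, 2, 3), c(101, 102, 103)))
  same <- compare_latencies(mk(c(1, 2, 3), "a"), mk(c(1, 2, 3), "b"))
  expect_gt(same$p_value, 0.99)
  ## shift alternative with large n rejects
  set.seed(4)
  big <- compare_latencies(mk(rnorm(40, 1.2, 0.3), "a"),
                           mk(rnorm(40, 1.8, 0.3), "b"))
  expect_lt(big$p_value, 0.05)
})

test_that("thin_onsets enforces the minimum spacing greedily", {
  expect_equal(thin_onsets(c(0, 5, 21, 30, 45), 20), c(0, 21, 45))
  expect_equal(thin_onsets(numeric(0)), numeric(0))
})
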