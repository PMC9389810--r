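test_that("age-adjusted mean declines at the configured rate", {
  expect_equal(age_adjusted_mean(85.07, 0), 85.07)
  expect_equal(age_adjusted_mean(85.07, 10), 76.97)
  expect_equal(age_adjusted_mean(90, 1), 89.19)
  expect_equal(age_adjusted_mean(90, 1, decline_rate = 0), 90)
  expect_error(age_adjusted_mean(85, -0.5), "non-negative")
})

test_that("a single CUSUM step accumulates shortfall and caps at zero", {
  mu <- 85; sigma <- 7.8
  expect_equal(cusum_step(0, mu, mu, sigma, 0.75), 0)
  expect_equal(cusum_step(0, mu - 2 * sigma, mu, sigma, 0.75), -1.25)
  expect_equal(cusum_step(-4, mu + 10 * sigma, mu, sigma, 0.75), 0)
  expect_error(cusum_step(0, 80, 85, 0, 0.75), "sigma")
  expect_error(cusum_step(0.5, 80, 85, 7.8, 0.75), "prev")
})

test_that("the full recursion matches the hand-computed trace and signals inclusively", {
  ref <- flat_ref(mu = 85, sigma = 10, decline_rate = 0)
  mk <- function(n) tibble::tibble(
    patient_id = "p", date = as.Date("2015-01-01") + seq_len(n) - 1,
    age = 50, egfr = 85 - 2 * 10)  # mu - 2 sigma at every visit
  tr3 <- run_cusum(mk(3), ref, w = 0.75, threshold = -4)
  expect_equal(tr3$cusum, c(-1.25, -2.50, -3.75))
  expect_false(any(tr3$signal))
  tr4 <- run_cusum(mk(4), ref, w = 0.75, threshold = -4)
  expect_equal(tr4$cusum, c(-1.25, -2.50, -3.75, -5.00))
  expect_equal(which(tr4$signal), 4L)

  # on-target series never accumulates (allowance absorbs nothing to absorb)
  flat <- flat_series("f", ref, n = 6)
  expect_equal(run_cusum(flat, ref, w = 0.75)$cusum, rep(0, 6))
})

test_that("signal detection returns the first inclusive crossing", {
  expect_equal(detect_signal(c(0, -1, -4.2, -5), -4), 3L)
  expect_equal(detect_signal(c(0, 0, 0), -4), NA_integer_)
  expect_equal(detect_signal(-4.0, -4.0), 1L)  # boundary is inclusive
  expect_error(detect_signal(c(0, -1), 1), "<= 0")
})

test_that("earliness is diagnosis minus signal in calendar days", {
  expect_equal(earliness_days(as.Date("2015-01-01"), as.Date("2015-12-28")),
               361L)
  expect_equal(earliness_days(as.Date("2015-05-05"), as.Date("2015-05-05")),
               0L)
  expect_equal(earliness_days(as.Date("2016-01-01"), as.Date("2015-01-01")),
               -365L)
})

test_that("run_cusum agrees with an independently coded recursion", {
  withr::local_seed(77)
  ref <- flat_ref()
  for (i in 1:100) {
    s <- random_series(sample(1:40, 1), start_age = runif(1, 40, 80))
    tr <- run_cusum(s, ref, w = 0.75)
    expect_equal(tr$cusum, naive_cusum(s, ref, 0.75), tolerance = 1e-12)
    expect_true(all(tr$cusum <= 0))
  }
})

test_that("traces are pointwise monotone in w and signal sets monotone in T", {
  withr::local_seed(78)
  ref <- flat_ref()
  for (i in 1:50) {
    s <- random_series(sample(3:30, 1))
    t1 <- run_cusum(s, ref, w = 0.25)$cusum
    t2 <- run_cusum(s, ref, w = 0.9)$cusum
    expect_true(all(t1 <= t2 + 1e-12))
    # a crossing at the stricter threshold implies one at the looser, earlier
    i1 <- detect_signal(t1, -5)
    i2 <- detect_signal(t1, -3)
    if (!is.na(i1)) {
      expect_false(is.na(i2))
      expect_lte(i2, i1)
    }
  }
})

test_that("the trace is invariant to a common rescaling of deviations and sigma", {
  withr::local_seed(79)
  ref <- flat_ref(mu = 85, sigma = 7.8, decline_rate = 0)
  s <- random_series(20)
  dev <- s$egfr - 85
  s2 <- s
  s2$egfr <- 85 + 3 * dev
  ref2 <- flat_ref(mu = 85, sigma = 3 * 7.8, decline_rate = 0)
  expect_equal(run_cusum(s, ref, w = 0.6)$cusum,
               run_cusum(s2, ref2, w = 0.6)$cusum, tolerance = 1e-12)
})

test_that("degenerate and malformed series are handled", {
  ref <- flat_ref()
  one <- random_series(1)
  expect_equal(nrow(run_cusum(one, ref)), 1L)
  expect_error(run_cusum(one[0, ], ref), "no observations")
  dup <- random_series(3)
  dup$date[2] <- dup$date[1]
  expect_error(run_cusum(dup, ref), "strictly increasing")
  expect_error(run_cusum(random_series(3), ref, w = -1), ">= 0")
})

test_that("signal_summary reports the first crossing per patient", {
  ref <- flat_ref(sigma = 10, decline_rate = 0)
  s1 <- steep_series("a", ref, n = 8)
  s2 <- flat_series("b", ref, n = 5)
  tr <- run_cusum(dplyr::bind_rows(s1, s2), ref, w = 0.75, threshold = -4)
  sm <- signal_summary(tr)
  expect_equal(nrow(sm), 2)
  a <- sm[sm$patient_id == "a", ]
  expect_true(a$signaled)
  expect_equal(a$signal_date, s1$date[a$signal_index])
  expect_equal(a$egfr_at_signal, s1$egfr[a$signal_index])
  expect_false(sm$signaled[sm$patient_id == "b"])
})
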