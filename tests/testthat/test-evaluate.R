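test_that("confusion metrics follow the standard definitions", {
  m <- confusion_metrics(data.frame(tp = 90, fn = 10, tn = 85, fp = 15))
  expect_equal(m$sensitivity, 0.900)
  expect_equal(m$specificity, 0.850)
  expect_equal(m$accuracy, 0.875)
  perfect <- confusion_metrics(data.frame(tp = 5410, fn = 0, tn = 85699, fp = 0))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$accuracy, 1)
  expect_error(confusion_metrics(data.frame(tp = 0, fn = 0, tn = 5, fp = 5)),
               "undefined metric")
})

test_that("classify_cohort separates a hand-built decliner from a flat control", {
  ref <- flat_ref(mu = 85, sigma = 10, decline_rate = 0)
  eskd <- steep_series("sick", ref, n = 8)
  dx_date <- max(eskd$date) + 30
  co <- make_cohort(normal_series = list(flat_series("well", ref, n = 8)),
                    eskd_series = list(eskd), diagnosis_dates = dx_date)
  ev <- classify_cohort(co, ref, w = 0.75, threshold = -4)
  expect_equal(as.integer(ev$counts[1, ]),
               c(1L, 0L, 1L, 0L), ignore_attr = TRUE)  # tp fp tn fn
  sick <- ev$signals[ev$signals$patient_id == "sick", ]
  expect_equal(sick$outcome, "tp")
  expect_true(sick$pre_diagnosis)
  expect_equal(sick$earliness,
               earliness_days(sick$signal_date, dx_date))
  m <- glance(ev)
  expect_equal(m$accuracy, 1)
})

test_that("post-diagnosis observations are never scored", {
  ref <- flat_ref(mu = 85, sigma = 10, decline_rate = 0)
  eskd <- steep_series("p", ref, n = 8)
  # diagnosis before the decline has accumulated: only 3 visits are scored
  dx_date <- eskd$date[4]
  co <- make_cohort(normal_series = list(flat_series("w", ref)),
                    eskd_series = list(eskd), diagnosis_dates = dx_date)
  ev <- classify_cohort(co, ref, w = 0.75, threshold = -4)
  expect_equal(ev$counts$fn, 1L)  # too little pre-diagnosis record to signal
  expect_equal(ev$counts$tp, 0L)
})

test_that("an empty cohort yields zero counts and undefined metrics error", {
  co <- make_cohort()
  ev <- classify_cohort(co, flat_ref())
  expect_equal(sum(as.integer(ev$counts[1, ])), 0L)
  expect_error(confusion_metrics(ev), "undefined metric")
})

test_that("earliness summaries aggregate true positives only", {
  sig <- tibble::tibble(
    outcome = c("tp", "tp", "tp", "fn", "fp"),
    earliness = c(100L, 200L, 300L, NA, NA),
    egfr_at_signal = c(65, 50, 25, NA, 40))
  s <- earliness_summary(sig)
  expect_equal(s$mean_earliness, 200)
  expect_equal(s$median_earliness, 200)
  expect_equal(s$se_earliness, sd(c(100, 200, 300)) / sqrt(3))
  expect_equal(s$pct_egfr_ge_30, 100 * 2 / 3)
  expect_equal(s$pct_egfr_ge_45, 100 * 2 / 3)
  expect_equal(s$pct_egfr_ge_60, 100 * 1 / 3)
  # post-diagnosis signals don't qualify
  late <- dplyr::mutate(sig, earliness = dplyr::if_else(outcome == "tp",
                                                        -10L, earliness))
  expect_error(earliness_summary(late), "no true positives")
})

test_that("subgroup stratification reproduces overall metrics for one level", {
  ref <- flat_ref(mu = 85, sigma = 10, decline_rate = 0)
  co <- make_cohort(
    normal_series = list(flat_series("n1", ref), flat_series("n2", ref)),
    eskd_series = list(steep_series("e1", ref), steep_series("e2", ref)),
    diagnosis_dates = rep(as.Date("2018-01-01"), 2),
    patient_extra = tibble::tibble(
      patient_id = c("n1", "n2", "e1", "e2"),
      everyone = "all", mixed = c("x", "y", "x", "y"),
      lopsided = c("x", "x", "x", "y")))
  ev <- classify_cohort(co, ref)
  one <- subgroup_performance(co, ev, "everyone")
  expect_equal(nrow(one), 1)
  expect_equal(one$accuracy, glance(ev)$accuracy)
  two <- subgroup_performance(co, ev, "mixed")
  expect_equal(nrow(two), 2)
  expect_true(all(two$defined))
  # a level with no ESKD patients is flagged undefined, not an error
  lop <- subgroup_performance(co, ev, "lopsided")
  expect_false(lop$defined[lop$level == "y"])
  expect_true(is.na(lop$sensitivity[lop$level == "y"]))
  expect_error(subgroup_performance(co, ev, "nope"), "stratifier")
})

test_that("longer pre-diagnosis records in a flagged subgroup raise its earliness", {
  ref <- flat_ref(mu = 85, sigma = 10, decline_rate = 0)
  long_records <- lapply(1:6, function(i)
    steep_series(paste0("L", i), ref, n = 14, drop_per_visit = 4))
  short_records <- lapply(1:6, function(i)
    steep_series(paste0("S", i), ref, n = 7, drop_per_visit = 8))
  dxs <- as.Date(vapply(c(long_records, short_records),
                        function(s) max(s$date) + 60, as.Date(NA)))
  co <- make_cohort(
    normal_series = lapply(1:4, function(i) flat_series(paste0("n", i), ref)),
    eskd_series = c(long_records, short_records),
    diagnosis_dates = dxs,
    patient_extra = tibble::tibble(
      patient_id = c(paste0("L", 1:6), paste0("S", 1:6), paste0("n", 1:4)),
      flagged = c(rep(TRUE, 6), rep(FALSE, 6), rep(FALSE, 4))))
  ev <- classify_cohort(co, ref)
  sub <- subgroup_performance(co, ev, "flagged")
  e_true <- sub$mean_earliness[sub$level == "TRUE"]
  e_false <- sub$mean_earliness[sub$level == "FALSE"]
  expect_gt(e_true, e_false)
})
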