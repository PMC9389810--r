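dated <- function(...) as.Date(c(...))

test_that("ICD matching is exact unless the pattern carries a wildcard", {
  expect_equal(icd_match(c("N18.6", "N18.3", "585.6", "585.61"),
                         c("585.6", "N18.6")),
               c(TRUE, FALSE, TRUE, FALSE))
  expect_true(all(icd_match(c("N18.1", "N18.9", "n18.6"), "N18*")))
  expect_false(icd_match("N19", "N18*"))
  expect_true(icd_match(" n18.6 ", "N18.6"))  # whitespace/case tolerated
})

test_that("ESKD labels use the earliest matching dated code", {
  dx <- tibble::tibble(
    patient_id = c("a", "a", "b", "c"),
    code = c("N18.6", "585.6", "N18.3", "N18.6"),
    date = dated("2018-03-01", "2017-06-15", "2018-01-01", "2019-01-01"))
  lab <- assign_groups(dx)
  expect_equal(sort(lab$patient_id), c("a", "c"))
  expect_equal(lab$diagnosis_date[lab$patient_id == "a"],
               as.Date("2017-06-15"))
  dx$date[1] <- NA
  expect_error(assign_groups(dx), "without a date")
  expect_error(assign_groups(dx, eskd_codes = character(0)), "non-empty")
})

test_that("the acute-kidney-injury rule excludes short all-low records only", {
  short_low <- tibble::tibble(patient_id = "s",
                              date = dated("2015-01-01") + c(0, 20, 40, 60),
                              egfr = c(70, 75, 80, 85))
  short_mixed <- dplyr::mutate(short_low, patient_id = "m",
                               egfr = c(70, 75, 92, 85))
  long_low <- dplyr::mutate(short_low, patient_id = "l",
                            date = dated("2015-01-01") + c(0, 200, 400, 730))
  out <- exclude_aki(dplyr::bind_rows(short_low, short_mixed, long_low))
  expect_equal(out$excluded$patient_id, "s")
  expect_equal(out$excluded$reason, "acute_kidney_injury")
  expect_setequal(unique(out$labs$patient_id), c("m", "l"))
})

test_that("Normal-Group selection applies the code, floor and count rules in order", {
  mk <- function(id, egfrs) tibble::tibble(
    patient_id = id, date = dated("2015-01-01") + seq_along(egfrs) * 100,
    egfr = egfrs)
  labs <- dplyr::bind_rows(
    mk("keep", rep(c(72, 80, 95), length.out = 10)),
    mk("low", c(rep(90, 11), 58)),
    mk("few", rep(c(65, 90), 4)),
    mk("ckd", rep(85, 12)),
    mk("eskd1", rep(85, 12)))
  dx <- tibble::tibble(patient_id = "ckd", code = "N18.3",
                       date = dated("2016-01-01"))
  out <- select_normal(labs, dx, eskd_ids = "eskd1")
  expect_equal(out$patient_ids, "keep")
  expect_equal(
    out$excluded$reason[match(c("low", "few", "ckd"), out$excluded$patient_id)],
    c("egfr_below_60", "too_few_measurements", "ckd_exclusion_code"))
  expect_false("eskd1" %in% c(out$patient_ids, out$excluded$patient_id))
})

test_that("ESKD-Group selection enforces the initial-eGFR floor inclusively", {
  mk <- function(id, egfrs, dates) tibble::tibble(
    patient_id = id, date = dates, egfr = egfrs)
  d <- dated("2014-01-01") + c(0, 300, 600, 900)
  labs <- dplyr::bind_rows(
    mk("ok", c(75, 68, 50, 30), d),
    mk("low0", c(45, 40, 30, 20), d),
    mk("edge", c(60, 55, 40, 25), d),
    mk("late", c(80, 70, 60, 50), d))
  eskd <- tibble::tibble(
    patient_id = c("ok", "low0", "edge", "late"),
    diagnosis_date = c(dated("2017-01-01"), dated("2017-01-01"),
                       dated("2017-01-01"), dated("2014-02-01")))
  out <- select_eskd(labs, eskd)
  expect_setequal(out$patients$patient_id, c("ok", "edge"))
  expect_equal(
    out$excluded$reason[match(c("low0", "late"), out$excluded$patient_id)],
    c("initial_egfr_below_60", "too_few_pre_diagnosis_obs"))
})

test_that("build_cohort accounts for every patient and keeps groups disjoint", {
  cfg <- sim_config(n_normal = 60, n_progressor = 20, seed = 12,
                    decoys_per_type = 2)
  sim <- simulate_cohort(cfg)
  co <- build_cohort(sim$labs, sim$demographics, sim$diagnoses)
  n_in <- dplyr::n_distinct(sim$labs$patient_id)
  expect_equal(nrow(co$patients) + nrow(co$exclusion_log), n_in)
  expect_length(intersect(co$patients$patient_id[co$patients$group == "normal"],
                          co$patients$patient_id[co$patients$group == "eskd"]),
                0)
  # selection invariants on the retained labs
  normal_labs <- cohort_labs(co, "normal")
  expect_true(all(normal_labs$egfr >= 60))
  expect_true(all(dplyr::count(normal_labs, patient_id)$n >= 9))
  first_eskd <- cohort_labs(co, "eskd", pre_diagnosis_only = FALSE) |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(first = egfr[which.min(date)])
  expect_true(all(first_eskd$first >= 60))
  # every exclusion carries a stage and reason
  expect_false(anyNA(co$exclusion_log$reason))
  expect_false(anyNA(co$exclusion_log$stage))
})
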