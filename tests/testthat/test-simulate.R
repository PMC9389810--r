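test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_normal = 20, n_progressor = 8, seed = 123,
                    decoys_per_type = 1)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$labs, s2$labs)
  expect_identical(s1$demographics, s2$demographics)
  expect_identical(s1$diagnoses, s2$diagnoses)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(sim_config(n_normal = 20, n_progressor = 8,
                                   seed = 124, decoys_per_type = 1))
  expect_false(identical(s1$labs, s3$labs))
})

test_that("simulated patients satisfy the series and selection invariants", {
  cfg <- sim_config(n_normal = 40, n_progressor = 15, seed = 5)
  sim <- simulate_cohort(cfg)
  labs <- add_egfr(sim$labs, sim$demographics)
  per <- labs |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(n = dplyr::n(), min_egfr = min(egfr),
                     first_egfr = egfr[which.min(date)],
                     increasing = all(diff(as.numeric(date)) > 0))
  expect_true(all(per$increasing))
  normals <- per[per$patient_id %in%
                   sim$truth$patient_id[sim$truth$role == "normal"], ]
  expect_true(all(normals$n >= 9))
  expect_true(all(normals$min_egfr >= 60))
  prog_ids <- sim$truth$patient_id[sim$truth$role == "progressor"]
  progs <- per[per$patient_id %in% prog_ids, ]
  expect_true(all(progs$first_egfr >= 60))
  # >= 2 observations strictly before every diagnosis date
  pre_counts <- labs |>
    dplyr::inner_join(sim$truth[sim$truth$role == "progressor",
                                c("patient_id", "diagnosis_date")],
                      by = "patient_id") |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(n_pre = sum(date < diagnosis_date))
  expect_true(all(pre_counts$n_pre >= 2))
  # every progressor carries exactly one dated ESKD code
  expect_setequal(sim$diagnoses$patient_id, prog_ids)
  expect_true(all(sim$diagnoses$code %in% c("585.6", "N18.6")))
})

test_that("zero noise collapses normal series onto the linear latent decline", {
  cfg <- sim_config(n_normal = 3, n_progressor = 0, seed = 8, normal_sd = 0)
  sim <- simulate_cohort(cfg)
  labs <- add_egfr(sim$labs, sim$demographics)
  one <- labs[labs$patient_id == labs$patient_id[1], ]
  t_years <- as.numeric(one$date - one$date[1]) / 365.25
  expect_equal(one$egfr, one$egfr[1] - cfg$normal_decline * t_years,
               tolerance = 1e-6)
})

test_that("degenerate progressor slopes exhaust retries with a config error", {
  cfg <- sim_config(n_normal = 0, n_progressor = 1, seed = 3,
                    trajectory_mix = c(rapid = 0, slow = 1, nonlinear = 0),
                    slow_slope = c(0, 0))
  expect_error(simulate_cohort(cfg), "never reached")
})

test_that("an entry-mean schedule touching the floor is rejected up front", {
  expect_error(sim_config(normal_mean_ref = 62), "infeasible")
})

test_that("the diagnosis date is the closed-form latent threshold crossing", {
  cfg <- sim_config(n_normal = 0, n_progressor = 6, seed = 21, normal_sd = 0,
                    trajectory_mix = c(rapid = 1, slow = 0, nonlinear = 0),
                    rapid_changepoint_years = c(3, 3), rapid_slope = c(15, 15))
  sim <- simulate_cohort(cfg)
  labs <- add_egfr(sim$labs, sim$demographics)
  for (pid in sim$truth$patient_id) {
    one <- labs[labs$patient_id == pid, ]
    e0 <- one$egfr[1]  # noise-free: first observation is the latent entry value
    t_star_expected <- 3 + (e0 - 0.81 * 3 - cfg$diagnosis_threshold) / 15
    dx <- sim$truth$diagnosis_date[sim$truth$patient_id == pid]
    t_star_actual <- as.numeric(dx - one$date[1]) / 365.25
    expect_equal(t_star_actual, t_star_expected, tolerance = 0.01)
  }
})

test_that("comorbidity prevalences match their configured rates", {
  cfg <- sim_config(n_normal = 50, n_progressor = 300, seed = 31)
  sim <- simulate_cohort(cfg)
  prog <- sim$demographics[sim$demographics$patient_id %in%
                             sim$truth$patient_id[sim$truth$role == "progressor"], ]
  p_hat <- mean(prog$hypertension)
  p0 <- cfg$prevalence$hypertension[["progressor"]]
  expect_lt(abs(p_hat - p0), 3 * sqrt(p0 * (1 - p0) / nrow(prog)))
})

test_that("AR(1) noise mode respects the Normal-Group floor", {
  cfg <- sim_config(n_normal = 10, n_progressor = 0, seed = 41, ar1_rho = 0.5)
  sim <- simulate_cohort(cfg)
  labs <- add_egfr(sim$labs, sim$demographics)
  expect_true(all(labs$egfr >= 60))
})

test_that("decoy patients violate exactly the rule they are built for", {
  cfg <- sim_config(n_normal = 15, n_progressor = 8, seed = 61,
                    decoys_per_type = 2)
  sim <- simulate_cohort(cfg)
  co <- build_cohort(sim$labs, sim$demographics, sim$diagnoses)
  decoys <- sim$truth[sim$truth$role == "decoy", ]
  log <- co$exclusion_log
  for (i in seq_len(nrow(decoys))) {
    row <- log[log$patient_id == decoys$patient_id[i], ]
    expect_equal(nrow(row), 1)
    expect_equal(row$stage, decoys$expected_stage[i])
    expect_equal(row$reason, decoys$expected_reason[i])
  }
  kept <- sim$truth$patient_id[sim$truth$role != "decoy"]
  expect_setequal(co$patients$patient_id, kept)
})
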