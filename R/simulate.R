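# Seeded generator of labeled longitudinal cohorts with the statistical
# structure the CUSUM assumes: normal patients fluctuating around an
# age-declining mean, progressors with heterogeneous decline trajectories
# ending in an ESKD diagnosis, irregular visit gaps, and optional "decoy"
# patients violating each selection rule so the cohort builder can be
# checked against ground truth.

#' Configuration for the synthetic cohort generator
#'
#' All rates and scales the generator uses, with defaults anchored to the
#' cohort structure the method targets: Normal-Group mean eGFR 85.07
#' mL/min/1.73 m^2 at the reference age, visit noise SD 7.8, healthy
#' decline 0.81 mL/min/1.73 m^2/yr, mean ages 64.5 (normal) / 57.9
#' (progressor), dispersed ~120-day visit gaps, and comorbidity
#' prevalences by group. The entry-mean schedule is
#' `mu_entry(age) = normal_mean_ref + normal_decline * (ref_age - age)`,
#' i.e. the per-age means follow the same annual decline the statistic
#' adjusts for.
#'
#' @param n_normal,n_progressor Patients per group.
#' @param seed Integer seed; fixes every random draw in
#'   [simulate_cohort()].
#' @param start_date,enrol_window_years First-visit dates are spread
#'   uniformly over this calendar window.
#' @param entry_age_mean Named vector, mean entry age per group.
#' @param entry_age_sd,entry_age_range Entry-age dispersion and truncation
#'   bounds (years).
#' @param gap_mean_days,gap_dispersion Visit gaps are
#'   `1 + NegBin(mu = gap_mean_days - 1, size = gap_dispersion)` days.
#' @param follow_up_years Nominal Normal-Group follow-up span.
#' @param max_follow_up_years Progressor trajectories must reach the
#'   diagnosis threshold within this horizon (resampled otherwise).
#' @param min_visits Minimum visits per Normal patient (default 9, the
#'   Normal-Group inclusion floor).
#' @param normal_mean_ref,ref_age Mean eGFR at the reference age.
#' @param normal_sd Visit-level noise SD, mL/min/1.73 m^2.
#' @param normal_decline Healthy annual decline, mL/min/1.73 m^2/yr.
#' @param normal_floor Normal-Group values below this are redrawn
#'   (truncation), matching the group's "no eGFR < 60" definition.
#' @param trajectory_mix Named proportions of progressor shapes
#'   (`rapid`, `slow`, `nonlinear`), summing to 1.
#' @param rapid_changepoint_years,rapid_slope Rapid shape: stable (healthy
#'   decline) until a change point, then a steep linear drop (slope range,
#'   mL/min/1.73 m^2/yr).
#' @param slow_slope Slow shape: constant steep slope range.
#' @param nonlinear_asymptote,nonlinear_tau_years Nonlinear shape: convex
#'   exponential decay toward an asymptote with the given time constant.
#' @param progressor_entry_min Minimum latent entry eGFR for progressors
#'   (keeps the first measurement above the ESKD-group inclusion floor).
#' @param diagnosis_threshold Latent eGFR whose first crossing defines the
#'   ESKD diagnosis date (default 15, the dialysis-range boundary).
#' @param post_diagnosis_fraction Fraction of progressors with
#'   observations continuing past diagnosis.
#' @param female_prob Named vector, probability of female sex per group.
#' @param race_probs List of named probability vectors per group.
#' @param prevalence List of comorbidity-flag prevalences, each a
#'   length-2 vector `(normal, progressor)`.
#' @param ar1_rho Optional AR(1) correlation of visit noise (default 0,
#'   independent noise).
#' @param decoys_per_type Number of decoy patients per violated rule
#'   (default 0; see [simulate_cohort()]).
#' @param icd9_fraction Fraction of ESKD diagnoses coded as ICD-9 585.6
#'   rather than ICD-10 N18.6.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_normal = 200, n_progressor = 50, seed = 1L,
                       start_date = as.Date("2012-01-01"),
                       enrol_window_years = 4,
                       entry_age_mean = c(normal = 64.5, progressor = 57.9),
                       entry_age_sd = 10, entry_age_range = c(35, 85),
                       gap_mean_days = 120, gap_dispersion = 2,
                       follow_up_years = 6, max_follow_up_years = 12,
                       min_visits = 9,
                       normal_mean_ref = 85.07, ref_age = 64.5,
                       normal_sd = 7.8, normal_decline = 0.81,
                       normal_floor = 60,
                       trajectory_mix = c(rapid = 0.4, slow = 0.4,
                                          nonlinear = 0.2),
                       rapid_changepoint_years = c(1, 4),
                       rapid_slope = c(10, 20),
                       slow_slope = c(6, 12),
                       nonlinear_asymptote = c(0, 10),
                       nonlinear_tau_years = c(1.5, 4),
                       progressor_entry_min = 65,
                       diagnosis_threshold = 15,
                       post_diagnosis_fraction = 0.3,
                       female_prob = c(normal = 0.54, progressor = 0.44),
                       race_probs = list(
                         normal = c(white = 0.81, black = 0.07, other = 0.12),
                         progressor = c(white = 0.67, black = 0.21, other = 0.12)),
                       prevalence = list(
                         hypertension = c(normal = 0.54, progressor = 0.89),
                         diabetes = c(normal = 0.26, progressor = 0.63),
                         cardiovascular = c(normal = 0.15, progressor = 0.43),
                         hypercholesterolemia = c(normal = 0.57, progressor = 0.63),
                         smoking = c(normal = 0.18, progressor = 0.45)),
                       ar1_rho = 0, decoys_per_type = 0,
                       icd9_fraction = 0.15) {
  cfg <- as.list(environment())
  if (abs(sum(trajectory_mix) - 1) > 1e-8) {
    abort_input("`trajectory_mix` proportions must sum to 1")
  }
  if (!all(c("rapid", "slow", "nonlinear") %in% names(trajectory_mix))) {
    abort_input("`trajectory_mix` must name rapid, slow and nonlinear")
  }
  if (normal_sd < 0 || gap_mean_days <= 1 || normal_decline < 0) {
    abort_input("scales must be positive")
  }
  if (ar1_rho < 0 || ar1_rho >= 1) abort_input("`ar1_rho` must be in [0, 1)")
  mu_oldest <- normal_mean_ref +
    normal_decline * (ref_age - (entry_age_range[2] + follow_up_years))
  if (mu_oldest <= normal_floor + 1) {
    abort_input(paste0(
      "infeasible config: entry-mean schedule reaches the Normal-Group ",
      "floor (%g <= %g) for the oldest patients"), mu_oldest, normal_floor + 1)
  }
  structure(cfg, class = "sim_config")
}

mu_entry <- function(cfg, age) {
  cfg$normal_mean_ref + cfg$normal_decline * (cfg$ref_age - age)
}

# irregular visit times in years: day gaps are 1 + NegBin
visit_times <- function(cfg, span_years, min_visits) {
  n_guess <- max(min_visits, ceiling(span_years * 366 / cfg$gap_mean_days) + 8)
  gaps <- 1 + rnbinom(n_guess, size = cfg$gap_dispersion,
                      mu = cfg$gap_mean_days - 1)
  t <- cumsum(c(0, gaps)) / 365.25
  inside <- t[t <= span_years]
  while (length(inside) < min_visits && length(inside) < length(t)) {
    inside <- t[seq_len(length(inside) + 1)]
  }
  if (length(inside) < min_visits) {
    extra <- 1 + rnbinom(min_visits, size = cfg$gap_dispersion,
                         mu = cfg$gap_mean_days - 1)
    inside <- cumsum(c(0, c(gaps, extra)))[seq_len(min_visits)] / 365.25
  }
  inside
}

# visit noise around a latent trajectory; elementwise truncation below
# `lower`, optional AR(1) correlation (redraw whole series if truncated)
visit_noise <- function(cfg, latent, lower = -Inf) {
  n <- length(latent)
  if (cfg$ar1_rho == 0) {
    return(rtnorm(n, latent, cfg$normal_sd, lower = lower) - latent)
  }
  for (i in seq_len(100)) {
    z <- rnorm(n)
    e <- numeric(n)
    e[1] <- z[1]
    for (j in seq_len(n - 1)) {
      e[j + 1] <- cfg$ar1_rho * e[j] + sqrt(1 - cfg$ar1_rho^2) * z[j + 1]
    }
    e <- e * cfg$normal_sd
    if (all(latent + e >= lower)) return(e)
  }
  abort_input("could not draw AR(1) noise above the floor; check config")
}

sim_demographics <- function(cfg, patient_id, group, age0, entry_date) {
  p <- function(x) unname(x[[if (group == "normal") 1L else 2L]])
  tibble(
    patient_id = patient_id,
    sex = sample(c("female", "male"), 1,
                 prob = c(p(cfg$female_prob), 1 - p(cfg$female_prob))),
    birth_date = entry_date - round(age0 * 365.25),
    race = sample(names(cfg$race_probs[[if (group == "normal") "normal" else
                                          "progressor"]]), 1,
                  prob = cfg$race_probs[[if (group == "normal") "normal" else
                                           "progressor"]]),
    hypertension = runif(1) < p(cfg$prevalence$hypertension),
    diabetes = runif(1) < p(cfg$prevalence$diabetes),
    cardiovascular = runif(1) < p(cfg$prevalence$cardiovascular),
    hypercholesterolemia = runif(1) < p(cfg$prevalence$hypercholesterolemia),
    smoking = runif(1) < p(cfg$prevalence$smoking)
  )
}

labs_from_values <- function(cfg, patient_id, entry_date, t, egfr, age0, sex) {
  tibble(
    patient_id = patient_id,
    date = entry_date + round(t * 365.25),
    scr = invert_ckd_epi(egfr, age0 + t, sex)
  )
}

#' Simulate one Normal-Group patient
#'
#' Latent eGFR declines from the entry-mean schedule at the healthy rate;
#' observed values add independent (or AR(1)) Gaussian visit noise,
#' redrawn from the truncated normal when below the Normal-Group floor of
#' 60. At least `min_visits` visits are guaranteed.
#'
#' @param cfg A [sim_config()].
#' @param patient_id Identifier for the emitted rows.
#' @return List with `labs` (patient_id, date, scr), `demographics`, and
#'   `latent` (the noise-free trajectory, for tests).
#' @export
simulate_normal_patient <- function(cfg, patient_id = "N0001") {
  age0 <- rtnorm(1, cfg$entry_age_mean[["normal"]], cfg$entry_age_sd,
                 cfg$entry_age_range[1], cfg$entry_age_range[2])
  entry_date <- cfg$start_date +
    floor(runif(1, 0, cfg$enrol_window_years * 365.25))
  t <- visit_times(cfg, cfg$follow_up_years, cfg$min_visits)
  latent <- mu_entry(cfg, age0) - cfg$normal_decline * t
  if (any(latent <= cfg$normal_floor)) {
    abort_input("infeasible config: latent normal trajectory below the floor")
  }
  egfr <- latent + visit_noise(cfg, latent, lower = cfg$normal_floor)
  demo <- sim_demographics(cfg, patient_id, "normal", age0, entry_date)
  list(labs = labs_from_values(cfg, patient_id, entry_date, t, egfr, age0,
                               demo$sex),
       demographics = demo, latent = latent)
}

# sample a trajectory shape and its latent function + threshold crossing
sample_trajectory <- function(cfg) {
  for (i in seq_len(100)) {
    shape <- sample(names(cfg$trajectory_mix), 1, prob = cfg$trajectory_mix)
    age0 <- rtnorm(1, cfg$entry_age_mean[["progressor"]], cfg$entry_age_sd,
                   cfg$entry_age_range[1], cfg$entry_age_range[2])
    e0 <- rtnorm(1, max(mu_entry(cfg, age0), cfg$progressor_entry_min + 5), 6,
                 lower = cfg$progressor_entry_min)
    thr <- cfg$diagnosis_threshold
    if (shape == "rapid") {
      tau <- runif(1, cfg$rapid_changepoint_years[1],
                   cfg$rapid_changepoint_years[2])
      s <- runif(1, cfg$rapid_slope[1], cfg$rapid_slope[2])
      t_star <- if (s > 0) tau + (e0 - cfg$normal_decline * tau - thr) / s else Inf
      latent_fun <- function(t) {
        ifelse(t < tau, e0 - cfg$normal_decline * t,
               e0 - cfg$normal_decline * tau - s * (t - tau))
      }
    } else if (shape == "slow") {
      s <- runif(1, cfg$slow_slope[1], cfg$slow_slope[2])
      t_star <- if (s > 0) (e0 - thr) / s else Inf
      latent_fun <- function(t) e0 - s * t
    } else {
      a <- runif(1, cfg$nonlinear_asymptote[1], cfg$nonlinear_asymptote[2])
      tau_d <- runif(1, cfg$nonlinear_tau_years[1], cfg$nonlinear_tau_years[2])
      t_star <- if (thr > a) tau_d * log((e0 - a) / (thr - a)) else Inf
      latent_fun <- function(t) a + (e0 - a) * exp(-t / tau_d)
    }
    if (is.finite(t_star) && t_star >= 1 && t_star <= cfg$max_follow_up_years) {
      return(list(shape = shape, age0 = age0, e0 = e0, t_star = t_star,
                  latent_fun = latent_fun))
    }
  }
  abort_input(paste0(
    "progressor trajectory never reached the diagnosis threshold within ",
    "the follow-up horizon after 100 attempts; check slope/threshold config"))
}

#' Simulate one ESKD-bound progressor
#'
#' The latent trajectory follows one of three shapes -- rapid (change point
#' then steep slope), slow-linear, or nonlinear (convex exponential decay)
#' -- and the diagnosis date is its first crossing of the diagnosis
#' threshold. The first observation is conditioned to be at least 60
#' mL/min/1.73 m^2, matching the ESKD-group inclusion rule; at least two
#' pre-diagnosis visits are guaranteed.
#'
#' @inheritParams simulate_normal_patient
#' @return List with `labs`, `demographics`, `diagnosis` (one diagnosis
#'   row with the ESKD ICD code dated at the latent crossing), `shape`,
#'   and `t_star` (years from entry to diagnosis).
#' @export
simulate_progressor <- function(cfg, patient_id = "P0001") {
  tr <- sample_trajectory(cfg)
  entry_date <- cfg$start_date +
    floor(runif(1, 0, cfg$enrol_window_years * 365.25))
  post_window <- if (runif(1) < cfg$post_diagnosis_fraction) {
    runif(1, 0.2, 1)
  } else 0
  t <- visit_times(cfg, tr$t_star + post_window, min_visits = 2)
  if (sum(t < tr$t_star) < 2) {
    t <- sort(unique(c(t, tr$t_star / 2)))
  }
  # latent floored at 4 mL/min/1.73m2: lower values imply creatinine far
  # outside the range seen in undialysed patients
  latent <- pmax(tr$latent_fun(t), 4)
  egfr <- latent + visit_noise(cfg, latent, lower = 4)
  # entry measurement conditioned >= 60 so inclusion reflects the latent state
  egfr[1] <- rtnorm(1, latent[1], cfg$normal_sd, lower = 60)
  demo <- sim_demographics(cfg, patient_id, "progressor", tr$age0, entry_date)
  diagnosis_date <- entry_date + round(tr$t_star * 365.25)
  icd9 <- runif(1) < cfg$icd9_fraction
  diagnosis <- tibble(
    patient_id = patient_id,
    icd_version = if (icd9) 9L else 10L,
    code = if (icd9) "585.6" else "N18.6",
    date = diagnosis_date)
  list(labs = labs_from_values(cfg, patient_id, entry_date, t, egfr,
                               tr$age0, demo$sex),
       demographics = demo, diagnosis = diagnosis,
       shape = tr$shape, t_star = tr$t_star)
}

# ---- decoys: patients built to violate exactly one selection rule ----

decoy_aki <- function(cfg, patient_id) {
  age0 <- rtnorm(1, cfg$entry_age_mean[["normal"]], cfg$entry_age_sd,
                 cfg$entry_age_range[1], cfg$entry_age_range[2])
  entry_date <- cfg$start_date +
    floor(runif(1, 0, cfg$enrol_window_years * 365.25))
  t <- c(0, 15, 35, 60) / 365.25
  egfr <- rtnorm(4, 75, 5, lower = 62, upper = 88)
  demo <- sim_demographics(cfg, patient_id, "normal", age0, entry_date)
  list(labs = labs_from_values(cfg, patient_id, entry_date, t, egfr, age0,
                               demo$sex),
       demographics = demo, diagnosis = NULL,
       stage = "aki_exclusion", reason = "acute_kidney_injury")
}

decoy_low_egfr <- function(cfg, patient_id) {
  p <- simulate_normal_patient(cfg, patient_id)
  demo <- p$demographics
  mid <- ceiling(nrow(p$labs) / 2)
  age_mid <- years_between(demo$birth_date, p$labs$date[mid])
  p$labs$scr[mid] <- invert_ckd_epi(rtnorm(1, 55, 2, 45, 59.5), age_mid,
                                    demo$sex)
  list(labs = p$labs, demographics = demo, diagnosis = NULL,
       stage = "normal_selection", reason = "egfr_below_60")
}

decoy_few_obs <- function(cfg, patient_id) {
  cfg8 <- cfg
  cfg8$min_visits <- 8
  cfg8$follow_up_years <- 8 * cfg$gap_mean_days / 365.25
  p <- simulate_normal_patient(cfg8, patient_id)
  keep <- seq_len(min(8, nrow(p$labs)))
  list(labs = p$labs[keep, ], demographics = p$demographics, diagnosis = NULL,
       stage = "normal_selection", reason = "too_few_measurements")
}

decoy_ckd_code <- function(cfg, patient_id) {
  p <- simulate_normal_patient(cfg, patient_id)
  mid_date <- p$labs$date[ceiling(nrow(p$labs) / 2)]
  list(labs = p$labs, demographics = p$demographics,
       diagnosis = tibble(patient_id = patient_id, icd_version = 10L,
                          code = "N18.3", date = mid_date),
       stage = "normal_selection", reason = "ckd_exclusion_code")
}

decoy_eskd_low_initial <- function(cfg, patient_id) {
  p <- simulate_progressor(cfg, patient_id)
  demo <- p$demographics
  age1 <- years_between(demo$birth_date, p$labs$date[1])
  p$labs$scr[1] <- invert_ckd_epi(rtnorm(1, 52, 4, 40, 59.5), age1, demo$sex)
  list(labs = p$labs, demographics = demo, diagnosis = p$diagnosis,
       stage = "eskd_selection", reason = "initial_egfr_below_60")
}

decoy_eskd_no_pre <- function(cfg, patient_id) {
  p <- simulate_progressor(cfg, patient_id)
  demo <- p$demographics
  dx <- p$diagnosis$date[1]
  # keep one pre-diagnosis visit (made non-AKI by a high first value) plus
  # any post-diagnosis visits
  age1 <- years_between(demo$birth_date, p$labs$date[1])
  p$labs$scr[1] <- invert_ckd_epi(rtnorm(1, 100, 4, 92, 115), age1, demo$sex)
  keep <- p$labs$date >= dx
  keep[1] <- TRUE
  labs <- p$labs[keep, ]
  if (nrow(labs) < 2) {
    post_date <- dx + 45
    age_post <- years_between(demo$birth_date, post_date)
    labs <- bind_rows(labs, tibble(
      patient_id = patient_id, date = post_date,
      scr = invert_ckd_epi(rtnorm(1, 12, 2, 6, 20), age_post, demo$sex)))
  }
  list(labs = labs, demographics = demo, diagnosis = p$diagnosis,
       stage = "eskd_selection", reason = "too_few_pre_diagnosis_obs")
}

#' Simulate a labeled longitudinal cohort
#'
#' Generates `n_normal` Normal-Group patients and `n_progressor`
#' ESKD-bound progressors (plus, optionally, `decoys_per_type` patients
#' per violated selection rule) and emits the three raw tables the cohort
#' builder consumes -- labs (creatinine), demographics, diagnoses -- plus a
#' ground-truth table. All randomness flows from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_cohort` list: `labs`, `demographics`, `diagnoses`,
#'   `truth` (patient_id, role, shape, diagnosis_date, expected exclusion
#'   stage/reason for decoys), and `config`.
#' @export
simulate_cohort <- function(cfg) {
  if (!inherits(cfg, "sim_config")) abort_input("`cfg` must be a sim_config")
  withr::with_seed(cfg$seed, {
    normals <- map(seq_len(cfg$n_normal), function(i) {
      simulate_normal_patient(cfg, sprintf("N%04d", i))
    })
    progressors <- map(seq_len(cfg$n_progressor), function(i) {
      simulate_progressor(cfg, sprintf("P%04d", i))
    })
    decoys <- list()
    if (cfg$decoys_per_type > 0) {
      makers <- list(aki = decoy_aki, low_egfr = decoy_low_egfr,
                     few_obs = decoy_few_obs, ckd_code = decoy_ckd_code,
                     eskd_low_initial = decoy_eskd_low_initial,
                     eskd_no_pre = decoy_eskd_no_pre)
      decoys <- unlist(lapply(names(makers), function(nm) {
        lapply(seq_len(cfg$decoys_per_type), function(i) {
          makers[[nm]](cfg, sprintf("D_%s_%02d", nm, i))
        })
      }), recursive = FALSE)
    }

    all_patients <- c(normals, progressors, decoys)
    labs <- list_rbind(map(all_patients, "labs"))
    demographics <- list_rbind(map(all_patients, "demographics"))
    diagnoses <- list_rbind(
      map(all_patients, function(p) p$diagnosis %||% NULL))
    if (is.null(diagnoses) || !nrow(diagnoses)) {
      diagnoses <- tibble(patient_id = character(0), icd_version = integer(0),
                          code = character(0), date = as.Date(character(0)))
    }
    truth <- bind_rows(
      tibble(patient_id = map_chr(normals, ~ .x$demographics$patient_id),
             role = "normal", shape = NA_character_,
             diagnosis_date = as.Date(NA),
             expected_stage = NA_character_, expected_reason = NA_character_),
      tibble(patient_id = map_chr(progressors, ~ .x$demographics$patient_id),
             role = "progressor", shape = map_chr(progressors, "shape"),
             diagnosis_date = as.Date(
               map_dbl(progressors, ~ as.numeric(.x$diagnosis$date[1]))),
             expected_stage = NA_character_, expected_reason = NA_character_),
      if (length(decoys)) {
        tibble(patient_id = map_chr(decoys, ~ .x$demographics$patient_id),
               role = "decoy", shape = NA_character_,
               diagnosis_date = as.Date(NA),
               expected_stage = map_chr(decoys, "stage"),
               expected_reason = map_chr(decoys, "reason"))
      }
    )
    structure(list(labs = labs, demographics = demographics,
                   diagnoses = diagnoses, truth = truth, config = cfg),
              class = "sim_cohort")
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic longitudinal cohort\n")
  cat(sprintf("  %d normal, %d progressor, %d decoy patients; %s lab rows (seed %d)\n",
              sum(x$truth$role == "normal"), sum(x$truth$role == "progressor"),
              sum(x$truth$role == "decoy"),
              format(nrow(x$labs), big.mark = ","), x$config$seed))
  invisible(x)
}
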