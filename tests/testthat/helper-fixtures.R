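# Fixtures and independent oracles shared across tests. Everything here is
# deliberately naive and separate from the package internals so it can
# serve as a cross-check of them.

# flat reference with a single-age table: every age falls back to the
# overall mean unless listed
flat_ref <- function(mu = 85, sigma = 7.8, decline_rate = 0.81) {
  new_gfr_reference(
    mu0_by_age = data.frame(age = 40:90, mean_egfr = mu),
    sigma = sigma, overall_mean = mu, decline_rate = decline_rate)
}

# a random measurement series as a lab table with precomputed egfr/age
random_series <- function(n_obs, patient_id = "x", start_age = 50,
                          mu = 85, sd_egfr = 12) {
  gaps <- sample(7:400, n_obs, replace = TRUE)
  dates <- as.Date("2014-06-01") + cumsum(c(0, gaps))[seq_len(n_obs)]
  tibble::tibble(
    patient_id = patient_id,
    date = dates,
    age = start_age + as.numeric(dates - dates[1]) / 365.25,
    egfr = pmax(rnorm(n_obs, mu, sd_egfr), 5)
  )
}

# independently coded CUSUM recursion: recomputes the age-adjusted mean and
# the accumulation from scratch with Reduce(accumulate = TRUE)
naive_cusum <- function(series, ref, w) {
  mu0 <- ref$mu0_by_age$mean_egfr[match(floor(series$age[1]),
                                        ref$mu0_by_age$age)]
  if (is.na(mu0)) mu0 <- ref$overall_mean
  dt <- as.numeric(series$date - series$date[1]) / 365.25
  mu_i <- mu0 - ref$decline_rate * dt
  z <- (series$egfr - mu_i) / ref$sigma + w
  Reduce(function(prev, zi) min(0, prev + zi), z,
         accumulate = TRUE, init = 0)[-1]
}

# hand-built labeled cohort: a list of lab tables (with egfr/age) per group.
# Bypasses build_cohort so evaluation tests control the series exactly.
make_cohort <- function(normal_series = list(), eskd_series = list(),
                        diagnosis_dates = as.Date(character(0)),
                        patient_extra = NULL) {
  normal_labs <- dplyr::bind_rows(normal_series)
  eskd_labs <- dplyr::bind_rows(eskd_series)
  labs <- dplyr::bind_rows(
    if (nrow(normal_labs)) dplyr::mutate(normal_labs, group = "normal"),
    if (nrow(eskd_labs)) dplyr::mutate(eskd_labs, group = "eskd"))
  patients <- dplyr::bind_rows(
    tibble::tibble(
      patient_id = vapply(normal_series, function(s) s$patient_id[1], ""),
      group = "normal", diagnosis_date = as.Date(NA)),
    tibble::tibble(
      patient_id = vapply(eskd_series, function(s) s$patient_id[1], ""),
      group = "eskd", diagnosis_date = diagnosis_dates))
  if (!is.null(patient_extra)) {
    patients <- dplyr::left_join(patients, patient_extra, by = "patient_id")
  }
  structure(
    list(labs = labs, patients = patients,
         exclusion_log = tibble::tibble(patient_id = character(0),
                                        stage = character(0),
                                        reason = character(0)),
         params = list()),
    class = "gfr_cohort")
}

# a steadily declining series guaranteed to signal, and a flat one that
# never does (deviations exactly on the reference mean)
steep_series <- function(id, ref, n = 8, drop_per_visit = 6) {
  dates <- as.Date("2015-01-01") + seq(0, by = 120, length.out = n)
  age <- 55 + as.numeric(dates - dates[1]) / 365.25
  mu_i <- ref$overall_mean - ref$decline_rate * (age - age[1])
  tibble::tibble(patient_id = id, date = dates, age = age,
                 egfr = mu_i - drop_per_visit * (seq_len(n) - 1))
}

flat_series <- function(id, ref, n = 8) {
  steep_series(id, ref, n = n, drop_per_visit = 0)
}
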