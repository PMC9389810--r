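#' Age-adjusted reference mean
#'
#' Projects the normal-group reference mean forward from a patient's first
#' measurement: \eqn{\hat\mu_i = \hat\mu_0 - d \cdot \Delta t}, where `d` is
#' the annual eGFR decline expected in healthy adults (default
#' 0.81 mL/min/1.73 m^2 per year) and \eqn{\Delta t} is elapsed time in
#' years since the first measurement.
#'
#' @param mu0 Reference mean eGFR at the patient's first measurement,
#'   mL/min/1.73 m^2.
#' @param delta_t Years elapsed since the first measurement, >= 0.
#' @param decline_rate Annual decline, mL/min/1.73 m^2 per year, >= 0.
#' @return `mu0 - decline_rate * delta_t`.
#' @export
age_adjusted_mean <- function(mu0, delta_t, decline_rate = 0.81) {
  if (anyNA(delta_t) || any(delta_t < 0)) {
    abort_input("`delta_t` must be non-negative (observations must be ordered)")
  }
  if (decline_rate < 0) abort_input("`decline_rate` must be >= 0")
  mu0 - decline_rate * delta_t
}

#' One step of the CUSUM-GFR recursion
#'
#' \deqn{C_i = \min\left[0, \frac{eGFR_i - \hat\mu_i}{\hat\sigma} + w +
#'   C_{i-1}\right]}
#' The minimum operator caps the statistic at zero so only persistent
#' downward shifts accumulate; recovery above the reference resets toward
#' zero but never above it.
#'
#' @param prev Previous CUSUM value, must be <= 0 (the statistic starts at
#'   0).
#' @param egfr Current eGFR measurement, mL/min/1.73 m^2.
#' @param mu Age-adjusted reference mean at this measurement.
#' @param sigma Reference standard deviation, > 0.
#' @param w Allowance: the per-observation standardized shift tolerated
#'   before accumulation, >= 0.
#' @return Updated CUSUM value, always <= 0.
#' @export
cusum_step <- function(prev, egfr, mu, sigma, w) {
  if (any(sigma <= 0)) abort_input("`sigma` must be > 0")
  if (any(w < 0)) abort_input("`w` must be >= 0")
  if (any(prev > 0)) abort_input("`prev` must be <= 0")
  pmin(0, (egfr - mu) / sigma + w + prev)
}

# full recursion over a standardized increment vector z_i = (x_i - mu_i)/sigma + w
cusum_path <- function(z) {
  out <- numeric(length(z))
  prev <- 0
  for (i in seq_along(z)) {
    prev <- min(0, z[i] + prev)
    out[i] <- prev
  }
  out
}

#' First threshold crossing of a CUSUM trace
#'
#' The signal is the first observation at which the statistic reaches the
#' threshold; the boundary is inclusive (a value exactly equal to `T`
#' signals). Monitoring continues afterwards -- later values are still
#' computed -- but only the first crossing is reported.
#'
#' @param values Numeric vector of CUSUM values (all <= 0).
#' @param threshold Signal threshold `T`, <= 0.
#' @return Integer index of the first `values[i] <= threshold`, or
#'   `NA_integer_` if the trace never signals.
#' @export
detect_signal <- function(values, threshold) {
  if (length(threshold) != 1 || is.na(threshold) || threshold > 0) {
    abort_input("`threshold` must be a single value <= 0")
  }
  idx <- which(values <= threshold)
  if (length(idx)) idx[1] else NA_integer_
}

#' Days from signal to diagnosis
#'
#' Earliness is `diagnosis_date - signal_date` in calendar days: positive
#' when the signal preceded diagnosis. Negative values (post-diagnosis
#' signals) are returned as-is; callers flag them as not-early.
#'
#' @param signal_date,diagnosis_date `Date` vectors.
#' @return Integer days.
#' @export
earliness_days <- function(signal_date, diagnosis_date) {
  check_date(signal_date, "`signal_date`")
  check_date(diagnosis_date, "`diagnosis_date`")
  as.integer(diagnosis_date - signal_date)
}

#' Run the CUSUM-GFR statistic over a lab table
#'
#' For each patient: looks up the reference mean \eqn{\hat\mu_0} at the
#' patient's integer age at their first measurement, projects it forward
#' with [age_adjusted_mean()], standardizes each eGFR deviation by the
#' pooled reference SD, adds the allowance `w`, and accumulates with the
#' zero-capped recursion of [cusum_step()] starting from 0. The CUSUM state
#' is never reset after a signal; the `signal` column marks the first
#' crossing only.
#'
#' @param labs Data frame with columns `patient_id`, `date` (Date, strictly
#'   increasing within patient), `egfr`, and `age` (years at measurement);
#'   the output of [add_egfr()] qualifies.
#' @param ref A [gfr_reference][estimate_reference] object.
#' @param w Allowance, >= 0 (default 0.75).
#' @param threshold Signal threshold `T`, <= 0 (default -4).
#' @return A `cusum_trace` tibble: one row per observation with `mu` (the
#'   age-adjusted reference mean), `cusum`, and logical `signal` marking the
#'   first crossing; `w` and `threshold` stored as attributes.
#' @seealso [signal_summary()] for the per-patient reduction,
#'   [autoplot.cusum_trace()] to plot traces.
#' @examples
#' ref <- new_gfr_reference(mu0_by_age = data.frame(age = 50, mean_egfr = 90),
#'                          sigma = 7.8, overall_mean = 90)
#' labs <- data.frame(patient_id = "p1",
#'                    date = as.Date("2015-01-01") + c(0, 120, 240),
#'                    egfr = c(88, 75, 62), age = 50 + c(0, 120, 240) / 365.25)
#' run_cusum(labs, ref)
#' @export
run_cusum <- function(labs, ref, w = 0.75, threshold = -4) {
  if (!inherits(ref, "gfr_reference")) {
    abort_input("`ref` must be a gfr_reference (see estimate_reference())")
  }
  check_columns(labs, c("patient_id", "date", "egfr", "age"), "`labs`")
  if (!nrow(labs)) abort_input("`labs` contains no observations")
  if (length(w) != 1 || is.na(w) || w < 0) {
    abort_input("`w` must be a single value >= 0")
  }
  check_date(labs$date, "`labs$date`")
  labs <- arrange(labs, .data$patient_id, .data$date)
  n <- nrow(labs)
  if (n > 1) {
    same <- labs$patient_id[-1] == labs$patient_id[-n]
    tied <- same & diff(as.numeric(labs$date)) <= 0
    if (any(tied)) {
      abort_input("dates must be strictly increasing within patient (%s)",
                  labs$patient_id[-1][tied][1])
    }
  }
  out <- labs |>
    group_by(.data$patient_id) |>
    mutate(
      delta_t = years_between(.data$date[1], .data$date),
      mu = age_adjusted_mean(
        mu0_at_age(ref, floor(.data$age[1])), .data$delta_t,
        ref$decline_rate),
      cusum = cusum_path((.data$egfr - .data$mu) / ref$sigma + w),
      signal = seq_along(.data$cusum) ==
        (detect_signal(.data$cusum, threshold) %||% 0L)
    ) |>
    ungroup() |>
    select(-"delta_t") |>
    as_tibble()
  out$signal[is.na(out$signal)] <- FALSE
  attr(out, "w") <- w
  attr(out, "threshold") <- threshold
  class(out) <- c("cusum_trace", class(out))
  out
}

#' Per-patient signal summary of a CUSUM trace
#'
#' Reduces a [run_cusum()] trace to one row per patient: whether and when
#' the patient first crossed the threshold, the eGFR at the signalling
#' observation, and the running minimum of the statistic.
#'
#' @param trace A `cusum_trace` tibble from [run_cusum()].
#' @param threshold Signal threshold; defaults to the one the trace was run
#'   with.
#' @return Tibble with columns `patient_id`, `n_obs`, `signaled`,
#'   `signal_index`, `signal_date`, `egfr_at_signal`, `min_cusum`.
#' @export
signal_summary <- function(trace, threshold = attr(trace, "threshold")) {
  check_columns(trace, c("patient_id", "date", "egfr", "cusum"), "`trace`")
  if (is.null(threshold)) abort_input("`threshold` is required")
  trace |>
    group_by(.data$patient_id) |>
    summarise(
      n_obs = n(),
      signal_index = detect_signal(.data$cusum, threshold),
      signaled = !is.na(.data$signal_index),
      signal_date = if (is.na(.data$signal_index)) as.Date(NA) else
        .data$date[.data$signal_index],
      egfr_at_signal = if (is.na(.data$signal_index)) NA_real_ else
        .data$egfr[.data$signal_index],
      min_cusum = min(.data$cusum),
      .groups = "drop"
    )
}
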