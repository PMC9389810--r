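#' Construct a normal-reference object directly
#'
#' Low-level constructor for the reference against which CUSUM deviations
#' are standardized: per-integer-age mean eGFR, a single pooled SD, and the
#' annual healthy decline rate. Most users should fit one from data with
#' [estimate_reference()]; the constructor exists for externally supplied
#' references (e.g. a health system's own per-age table) and for tests.
#'
#' @param mu0_by_age Data frame with columns `age` (integer years) and
#'   `mean_egfr` (mL/min/1.73 m^2, positive); an optional `n` column gives
#'   per-bin counts.
#' @param sigma Pooled SD of eGFR around the age means, > 0.
#' @param overall_mean Overall mean eGFR; used as fallback for ages missing
#'   from the table.
#' @param decline_rate Annual healthy decline, default 0.81
#'   mL/min/1.73 m^2/yr.
#' @param overall_se,n_obs Optional: standard error of the overall mean and
#'   number of measurements behind the estimate.
#' @return An object of class `gfr_reference`.
#' @export
new_gfr_reference <- function(mu0_by_age, sigma, overall_mean,
                              decline_rate = 0.81, overall_se = NA_real_,
                              n_obs = NA_integer_) {
  check_columns(mu0_by_age, c("age", "mean_egfr"), "`mu0_by_age`")
  if (!"n" %in% names(mu0_by_age)) mu0_by_age$n <- NA_integer_
  if (any(mu0_by_age$mean_egfr <= 0)) {
    abort_input("`mu0_by_age$mean_egfr` must be positive")
  }
  if (length(sigma) != 1 || is.na(sigma) || sigma <= 0) {
    abort_input("`sigma` must be a single value > 0")
  }
  if (decline_rate < 0) abort_input("`decline_rate` must be >= 0")
  structure(
    list(
      mu0_by_age = as_tibble(mu0_by_age[c("age", "mean_egfr", "n")]),
      sigma = sigma,
      decline_rate = decline_rate,
      overall_mean = overall_mean,
      overall_se = overall_se,
      n_obs = n_obs
    ),
    class = "gfr_reference"
  )
}

#' Estimate the normal reference from a Normal-Group lab table
#'
#' Computes the per-integer-age mean eGFR table \eqn{\hat\mu_0(a)} over all
#' Normal-Group measurements (age bin = floor of fractional age at the
#' measurement), the pooled SD \eqn{\hat\sigma} of the residuals around
#' those age means, and the overall mean with its standard error. The
#' pooled SD is the residual SD (denominator `n - #bins`), i.e. the spread
#' of eGFR around its age-specific mean, which is the scale on which the
#' CUSUM standardizes deviations.
#'
#' @param normal_labs Lab table of Normal-Group patients with `egfr` and
#'   `age` columns ([add_egfr()] output, typically `cohort$labs` filtered to
#'   the normal group).
#' @param decline_rate Annual healthy decline carried into the reference,
#'   default 0.81 mL/min/1.73 m^2/yr.
#' @param min_bin_n Age bins with fewer measurements than this fall back to
#'   the overall mean (recorded in the `n` column), default 10.
#' @return A `gfr_reference` object; see [new_gfr_reference()].
#' @export
estimate_reference <- function(normal_labs, decline_rate = 0.81,
                               min_bin_n = 10) {
  check_columns(normal_labs, c("egfr", "age"), "`normal_labs`")
  if (!nrow(normal_labs)) abort_input("`normal_labs` is empty")
  overall_mean <- mean(normal_labs$egfr)
  n <- nrow(normal_labs)
  overall_se <- sd(normal_labs$egfr) / sqrt(n)
  by_age <- normal_labs |>
    mutate(age_bin = floor(.data$age)) |>
    group_by(age = .data$age_bin) |>
    summarise(mean_egfr = mean(.data$egfr), n = n(), .groups = "drop")
  sparse <- by_age$n < min_bin_n
  if (any(sparse)) {
    by_age$mean_egfr[sparse] <- overall_mean
    message(sprintf(
      "%d age bin(s) with < %d measurements fell back to the overall mean",
      sum(sparse), min_bin_n))
  }
  resid <- normal_labs$egfr -
    by_age$mean_egfr[match(floor(normal_labs$age), by_age$age)]
  dof <- n - sum(!sparse)
  if (dof < 1) dof <- n - 1
  sigma <- sqrt(sum(resid^2) / max(dof, 1))
  if (!is.finite(sigma) || sigma <= 0) {
    abort_input("degenerate Normal Group: pooled SD is zero")
  }
  new_gfr_reference(by_age, sigma, overall_mean, decline_rate,
                    overall_se, n)
}

#' Look up the reference mean at an age
#'
#' Integer-age lookup into the reference table; ages not covered by the
#' table fall back to the overall mean.
#'
#' @param ref A `gfr_reference`.
#' @param age Integer age(s) in years (fractional input is floored).
#' @return Numeric vector of reference means.
#' @export
mu0_at_age <- function(ref, age) {
  if (!inherits(ref, "gfr_reference")) abort_input("`ref` must be a gfr_reference")
  mu <- ref$mu0_by_age$mean_egfr[match(floor(age), ref$mu0_by_age$age)]
  ifelse(is.na(mu), ref$overall_mean, mu)
}

#' @export
print.gfr_reference <- function(x, ...) {
  cat("Normal eGFR reference\n")
  cat(sprintf("  overall mean: %.2f mL/min/1.73m2 (se %.3g), n = %s\n",
              x$overall_mean, x$overall_se, format(x$n_obs, big.mark = ",")))
  cat(sprintf("  pooled SD:    %.3f\n", x$sigma))
  cat(sprintf("  decline rate: %.2f mL/min/1.73m2 per year\n", x$decline_rate))
  cat(sprintf("  age bins:     %d (ages %s-%s)\n", nrow(x$mu0_by_age),
              min(x$mu0_by_age$age), max(x$mu0_by_age$age)))
  invisible(x)
}

#' @describeIn estimate_reference `tidy()` returns the per-age mean table.
#' @param x,... broom-method arguments.
#' @method tidy gfr_reference
#' @export
tidy.gfr_reference <- function(x, ...) x$mu0_by_age

#' @describeIn estimate_reference `glance()` returns a one-row summary
#'   (overall mean, se, sigma, decline rate, n).
#' @method glance gfr_reference
#' @export
glance.gfr_reference <- function(x, ...) {
  tibble(overall_mean = x$overall_mean, overall_se = x$overall_se,
         sigma = x$sigma, decline_rate = x$decline_rate, n_obs = x$n_obs,
         n_age_bins = nrow(x$mu0_by_age))
}

#' Kolmogorov-Smirnov normality check of reference eGFR values
#'
#' One-sample KS test of the pooled Normal-Group eGFR values against a
#' normal distribution with the sample mean and SD, with a decision at the
#' given level. Used as a sanity check that the reference population is
#' well described by the (mean, SD) pair the CUSUM standardization relies
#' on.
#'
#' @param values Numeric vector of eGFR values, at least 20.
#' @param alpha Significance level for the reject/fail-to-reject decision,
#'   default 0.05.
#' @return A `gfr_ks` list: `statistic`, `p_value`, `n`, `mean`, `sd`,
#'   `alpha`, and logical `reject`.
#' @export
ks_normality_check <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 20) {
    abort_input("need at least 20 values for the KS normality check")
  }
  s <- sd(values)
  if (!is.finite(s) || s <= 0) {
    abort_input("degenerate input: values are identical")
  }
  kt <- suppressWarnings(
    ks.test(values, "pnorm", mean = mean(values), sd = s))
  structure(
    list(statistic = unname(kt$statistic), p_value = kt$p.value,
         n = length(values), mean = mean(values), sd = s,
         alpha = alpha, reject = kt$p.value < alpha),
    class = "gfr_ks")
}

#' Normality check of the Normal-Group reference distribution
#'
#' Applies [ks_normality_check()] to the *per-patient mean* eGFR of the
#' Normal Group. Repeated measurements within a patient share that
#' patient's age-level mean and are therefore not independent; pooling
#' them would violate the KS test's iid assumption and over-reject.
#' Aggregating to one mean per patient gives independent units, which is
#' also the natural reading of "the mean eGFR for the Normal Group" as the
#' quantity whose normality matters for the reference.
#'
#' @param normal_labs Normal-Group lab table with `patient_id` and `egfr`
#'   columns.
#' @param alpha Significance level, default 0.05.
#' @return A `gfr_ks` object; see [ks_normality_check()].
#' @export
reference_normality_check <- function(normal_labs, alpha = 0.05) {
  check_columns(normal_labs, c("patient_id", "egfr"), "`normal_labs`")
  per_patient <- normal_labs |>
    group_by(.data$patient_id) |>
    summarise(mean_egfr = mean(.data$egfr), .groups = "drop")
  ks_normality_check(per_patient$mean_egfr, alpha = alpha)
}

#' @export
print.gfr_ks <- function(x, ...) {
  cat(sprintf(
    "KS normality check: D = %.4f, p = %.3g, n = %d -> %s normality at alpha = %g\n",
    x$statistic, x$p_value, x$n,
    if (x$reject) "REJECT" else "fail to reject", x$alpha))
  invisible(x)
}
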