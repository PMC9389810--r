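#' Estimate GFR from serum creatinine (2021 CKD-EPI creatinine equation)
#'
#' Converts serum creatinine to estimated glomerular filtration rate using the
#' 2021 race-free refit of the CKD-EPI creatinine equation:
#' \deqn{eGFR = 142 \cdot \min(S_{cr}/\kappa, 1)^{\alpha} \cdot
#'   \max(S_{cr}/\kappa, 1)^{-1.200} \cdot 0.9938^{age} \cdot 1.012[\mathrm{female}]}
#' with \eqn{\kappa = 0.7} (female) / \eqn{0.9} (male) and
#' \eqn{\alpha = -0.241} (female) / \eqn{-0.302} (male). This is the adult
#' equation: ages below 18 are rejected.
#'
#' @param scr Serum creatinine, mg/dL. Must be positive; values above
#'   20 mg/dL are passed through with a warning as they are rarely
#'   physiologic.
#' @param age Age in years at the measurement (fractional ages welcome),
#'   must be >= 18.
#' @param sex `"female"` or `"male"` (case-insensitive). Recycled against
#'   `scr`/`age`.
#' @return Numeric vector of eGFR values, mL/min/1.73 m^2. Strictly
#'   decreasing in `scr` for fixed age and sex, and in `age` for fixed
#'   creatinine.
#' @seealso [invert_ckd_epi()] for the inverse map, [add_egfr()] to apply
#'   the equation to a lab table.
#' @examples
#' ckd_epi_2021(0.9, 50, "male")    # 142 * 0.9938^50 = 104.05
#' ckd_epi_2021(0.7, 50, "female")  # the same x 1.012
#' @export
ckd_epi_2021 <- function(scr, age, sex) {
  if (!length(scr)) return(numeric(0))
  sex <- check_sex(sex)
  n <- max(length(scr), length(age), length(sex))
  scr <- rep_len(scr, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  if (anyNA(scr) || any(scr <= 0)) abort_input("`scr` must be positive")
  if (anyNA(age) || any(age < 18)) {
    abort_input("`age` must be >= 18 (adult equation only)")
  }
  if (any(scr > 20)) {
    warning("serum creatinine > 20 mg/dL: passed through, check units",
            call. = FALSE)
  }
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.241, -0.302)
  ratio <- scr / kappa
  142 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^-1.200 *
    0.9938^age * ifelse(female, 1.012, 1)
}

#' Invert the 2021 CKD-EPI equation: eGFR back to serum creatinine
#'
#' Solves the piecewise power equation analytically on the branch consistent
#' with creatinine above/below the sex-specific knot \eqn{\kappa}, so the
#' round trip through [ckd_epi_2021()] is exact to floating-point precision.
#' Used by the cohort simulator so synthetic patients are emitted as raw
#' creatinine and the full pipeline (creatinine -> eGFR -> CUSUM) is
#' exercised.
#'
#' Targets are accepted only when the solving creatinine lies in a
#' physiologically plausible range (`scr_range`, default 0.01--100 mg/dL);
#' anything outside raises a domain error.
#'
#' @param egfr Target eGFR, mL/min/1.73 m^2, positive.
#' @param age Age in years, >= 18.
#' @param sex `"female"` or `"male"`.
#' @param scr_range Length-2 numeric, admissible creatinine interval in
#'   mg/dL defining the attainable eGFR range.
#' @return Serum creatinine in mg/dL such that
#'   `ckd_epi_2021(scr, age, sex) == egfr`.
#' @examples
#' invert_ckd_epi(104.05, 50, "male")  # ~0.9
#' @export
invert_ckd_epi <- function(egfr, age, sex, scr_range = c(0.01, 100)) {
  if (!length(egfr)) return(numeric(0))
  sex <- check_sex(sex)
  n <- max(length(egfr), length(age), length(sex))
  egfr <- rep_len(egfr, n); age <- rep_len(age, n); sex <- rep_len(sex, n)
  if (anyNA(egfr) || any(egfr <= 0)) abort_input("`egfr` must be positive")
  if (anyNA(age) || any(age < 18)) {
    abort_input("`age` must be >= 18 (adult equation only)")
  }
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.241, -0.302)
  base <- 142 * 0.9938^age * ifelse(female, 1.012, 1)  # value at scr = kappa
  r <- egfr / base
  # r >= 1: low-creatinine branch (scr <= kappa), r < 1: high branch
  scr <- ifelse(r >= 1, kappa * r^(1 / alpha), kappa * r^(-1 / 1.200))
  if (any(scr < scr_range[1] | scr > scr_range[2])) {
    abort_input(paste0(
      "target eGFR outside the attainable range for this age/sex ",
      "(implied creatinine outside [%g, %g] mg/dL)"), scr_range[1], scr_range[2])
  }
  scr
}

#' Attach age and eGFR columns to a longitudinal lab table
#'
#' Joins patient demographics onto per-measurement creatinine rows, computes
#' fractional age at each measurement date (actual/365.25 basis) and the
#' eGFR via [ckd_epi_2021()].
#'
#' @param labs Data frame with columns `patient_id`, `date` (Date), `scr`
#'   (mg/dL).
#' @param demographics Data frame with columns `patient_id`, `sex`,
#'   `birth_date` (Date), one row per patient.
#' @return A tibble: `labs` ordered by patient and date with `sex`, `age`
#'   and `egfr` columns added.
#' @export
add_egfr <- function(labs, demographics) {
  check_columns(labs, c("patient_id", "date", "scr"), "`labs`")
  check_columns(demographics, c("patient_id", "sex", "birth_date"),
                "`demographics`")
  check_date(labs$date, "`labs$date`")
  check_date(demographics$birth_date, "`demographics$birth_date`")
  if (anyDuplicated(demographics$patient_id)) {
    abort_input("`demographics` must have one row per patient")
  }
  missing_demo <- setdiff(labs$patient_id, demographics$patient_id)
  if (length(missing_demo)) {
    abort_input("no demographics for patient(s): %s",
                paste(head(missing_demo, 5), collapse = ", "))
  }
  labs |>
    inner_join(select(demographics, "patient_id", "sex", "birth_date"),
               by = "patient_id") |>
    mutate(
      sex = check_sex(.data$sex),
      age = years_between(.data$birth_date, .data$date),
      egfr = ckd_epi_2021(.data$scr, .data$age, .data$sex)
    ) |>
    select(-"birth_date") |>
    arrange(.data$patient_id, .data$date) |>
    as_tibble()
}
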