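# Selection pipeline: AKI exclusion -> group assignment from ICD codes ->
# ESKD-group filters -> Normal-group filters. Every exclusion is logged with
# a stage and reason so input count = retained + excluded at each stage.

#' Match ICD codes against a wildcard-aware code list
#'
#' Patterns ending in `*` match any code sharing the prefix (e.g. `"N18*"`
#' matches `N18.3`); other patterns match exactly. Matching is
#' case-insensitive and ignores surrounding whitespace.
#'
#' @param codes Character vector of ICD-9/ICD-10 codes.
#' @param patterns Character vector of code patterns.
#' @return Logical vector, `TRUE` where the code matches any pattern.
#' @export
icd_match <- function(codes, patterns) {
  codes <- toupper(trimws(as.character(codes)))
  patterns <- toupper(trimws(as.character(patterns)))
  hit <- rep(FALSE, length(codes))
  for (p in patterns) {
    if (endsWith(p, "*")) {
      hit <- hit | startsWith(codes, substr(p, 1, nchar(p) - 1))
    } else {
      hit <- hit | codes == p
    }
  }
  hit
}

#' Assign ESKD labels and diagnosis dates from a diagnosis table
#'
#' A patient is ESKD-labeled iff any diagnosis code matches the ESKD code
#' list (default ICD-9 585.6 / ICD-10 N18.6); the diagnosis date is the
#' earliest matching code date. A matching code without a date is a data
#' error.
#'
#' @param diagnoses Data frame with columns `patient_id`, `code`, `date`
#'   (Date); an `icd_version` column is carried but not required for
#'   matching.
#' @param eskd_codes Character vector of ESKD code patterns
#'   (wildcard-aware, see [icd_match()]).
#' @return Tibble with one row per ESKD-labeled patient: `patient_id`,
#'   `diagnosis_date`.
#' @export
assign_groups <- function(diagnoses, eskd_codes = c("585.6", "N18.6")) {
  if (!length(eskd_codes)) abort_input("`eskd_codes` must be non-empty")
  check_columns(diagnoses, c("patient_id", "code", "date"), "`diagnoses`")
  if (!nrow(diagnoses)) {
    return(tibble(patient_id = character(0), diagnosis_date = as.Date(character(0))))
  }
  hits <- diagnoses[icd_match(diagnoses$code, eskd_codes), , drop = FALSE]
  if (anyNA(hits$date)) {
    abort_input("ESKD diagnosis code without a date for patient(s): %s",
                paste(unique(hits$patient_id[is.na(hits$date)]), collapse = ", "))
  }
  hits |>
    group_by(.data$patient_id) |>
    summarise(diagnosis_date = min(.data$date), .groups = "drop")
}

#' Exclude acute kidney injury episodes
#'
#' Excludes patients whose record looks like an acute episode rather than a
#' chronic series: every eGFR below 90 mL/min/1.73 m^2 *and* the whole
#' record spanning at most `window_days` (default 92 days, i.e. three
#' months). Patients with long records are retained however low their
#' values (chronic, not acute).
#'
#' @param labs Lab table with `patient_id`, `date`, `egfr`.
#' @param window_days Maximum record span, in days, for the acute reading.
#' @return List with `labs` (rows of retained patients) and `excluded`
#'   (tibble `patient_id`, `reason = "acute_kidney_injury"`).
#' @export
exclude_aki <- function(labs, window_days = 92) {
  check_columns(labs, c("patient_id", "date", "egfr"), "`labs`")
  flag <- labs |>
    group_by(.data$patient_id) |>
    summarise(
      aki = all(.data$egfr < 90) &&
        as.numeric(max(.data$date) - min(.data$date)) <= window_days,
      .groups = "drop")
  out_ids <- flag$patient_id[flag$aki]
  list(
    labs = filter(labs, !.data$patient_id %in% out_ids),
    excluded = tibble(patient_id = out_ids,
                      reason = rep("acute_kidney_injury", length(out_ids)))
  )
}

#' Select the Normal Group
#'
#' From non-ESKD patients, retains those with no diagnosis code in the CKD
#' exclusion list, no eGFR below 60 anywhere in their record, and at least
#' `min_measurements` observations. Exclusion reasons are checked in that
#' order and the first failing rule is logged.
#'
#' @param labs Lab table (post-AKI exclusion) with `patient_id`, `egfr`.
#' @param diagnoses Diagnosis table (`patient_id`, `code`).
#' @param eskd_ids Character vector of ESKD-labeled patient ids (excluded
#'   from consideration here; the groups are mutually exclusive).
#' @param ckd_exclusion_codes Wildcard-aware CKD code patterns; any match
#'   excludes the patient from the Normal Group.
#' @param min_measurements Minimum number of observations, default 9.
#' @return List with `patient_ids` (retained Normal Group) and `excluded`
#'   (tibble `patient_id`, `reason`).
#' @export
select_normal <- function(labs, diagnoses, eskd_ids,
                          ckd_exclusion_codes = c("585*", "586", "N18*", "N19"),
                          min_measurements = 9) {
  check_columns(labs, c("patient_id", "egfr"), "`labs`")
  candidates <- setdiff(unique(labs$patient_id), eskd_ids)
  ckd_ids <- character(0)
  if (nrow(diagnoses)) {
    ckd_ids <- unique(diagnoses$patient_id[icd_match(diagnoses$code,
                                                     ckd_exclusion_codes)])
  }
  per <- labs |>
    filter(.data$patient_id %in% candidates) |>
    group_by(.data$patient_id) |>
    summarise(min_egfr = min(.data$egfr), n_obs = n(), .groups = "drop") |>
    mutate(
      reason = case_when(
        .data$patient_id %in% ckd_ids ~ "ckd_exclusion_code",
        .data$min_egfr < 60 ~ "egfr_below_60",
        .data$n_obs < min_measurements ~ "too_few_measurements",
        TRUE ~ NA_character_
      )
    )
  list(
    patient_ids = per$patient_id[is.na(per$reason)],
    excluded = per |> filter(!is.na(.data$reason)) |>
      select("patient_id", "reason")
  )
}

#' Select the ESKD Group
#'
#' Retains ESKD-labeled patients whose first eGFR is at least 60
#' mL/min/1.73 m^2 (boundary inclusive: exactly 60 is retained) and who
#' have at least `min_pre_diagnosis` observations strictly before the
#' diagnosis date, so a pre-diagnosis trace exists to score.
#'
#' @param labs Lab table (post-AKI exclusion).
#' @param eskd_labels Output of [assign_groups()]: `patient_id`,
#'   `diagnosis_date`.
#' @param min_pre_diagnosis Minimum pre-diagnosis observations, default 2.
#' @return List with `patients` (tibble `patient_id`, `diagnosis_date` of
#'   the retained ESKD Group) and `excluded` (tibble `patient_id`,
#'   `reason`).
#' @export
select_eskd <- function(labs, eskd_labels, min_pre_diagnosis = 2) {
  check_columns(eskd_labels, c("patient_id", "diagnosis_date"), "`eskd_labels`")
  per <- labs |>
    inner_join(eskd_labels, by = "patient_id") |>
    group_by(.data$patient_id) |>
    arrange(.data$date, .by_group = TRUE) |>
    summarise(
      first_egfr = .data$egfr[1],
      n_pre = sum(.data$date < .data$diagnosis_date[1]),
      diagnosis_date = .data$diagnosis_date[1],
      .groups = "drop") |>
    mutate(
      reason = case_when(
        .data$first_egfr < 60 ~ "initial_egfr_below_60",
        .data$n_pre < min_pre_diagnosis ~ "too_few_pre_diagnosis_obs",
        TRUE ~ NA_character_
      )
    )
  no_labs <- setdiff(eskd_labels$patient_id, labs$patient_id)
  excluded <- bind_rows(
    per |> filter(!is.na(.data$reason)) |> select("patient_id", "reason"),
    tibble(patient_id = no_labs,
           reason = rep("too_few_pre_diagnosis_obs", length(no_labs)))
  )
  list(
    patients = per |> filter(is.na(.data$reason)) |>
      select("patient_id", "diagnosis_date"),
    excluded = excluded
  )
}

#' Build a labeled cohort from longitudinal lab, demographic and diagnosis tables
#'
#' Runs the full selection pipeline: compute eGFR ([add_egfr()]), exclude
#' acute kidney injury ([exclude_aki()]), label ESKD patients from
#' diagnosis codes ([assign_groups()]), then apply the ESKD-group
#' ([select_eskd()]) and Normal-group ([select_normal()]) filters. Every
#' excluded patient appears in the exclusion log with the stage and the
#' first failing rule; the Normal and ESKD groups are mutually exclusive by
#' construction.
#'
#' @param labs Data frame `patient_id`, `date` (Date), `scr` (mg/dL).
#' @param demographics Data frame `patient_id`, `sex`, `birth_date`, plus
#'   any subgroup flag columns (carried through for stratified evaluation).
#' @param diagnoses Data frame `patient_id`, `icd_version`, `code`, `date`.
#' @param eskd_codes,ckd_exclusion_codes Wildcard-aware ICD code lists; see
#'   [assign_groups()] and [select_normal()].
#' @param min_measurements Normal-Group minimum observation count
#'   (default 9).
#' @param min_pre_diagnosis ESKD-Group minimum pre-diagnosis observation
#'   count (default 2).
#' @param aki_window_days Acute-episode window, default 92 days.
#' @return A `gfr_cohort` object: list with `labs` (retained rows with
#'   `age`, `egfr`, `group`), `patients` (one row per retained patient:
#'   demographics, `group`, `diagnosis_date`), `exclusion_log`
#'   (`patient_id`, `stage`, `reason`) and `params`.
#' @export
build_cohort <- function(labs, demographics, diagnoses,
                         eskd_codes = c("585.6", "N18.6"),
                         ckd_exclusion_codes = c("585*", "586", "N18*", "N19"),
                         min_measurements = 9, min_pre_diagnosis = 2,
                         aki_window_days = 92) {
  labs <- add_egfr(labs, demographics)
  if (!nrow(diagnoses)) {
    diagnoses <- tibble(patient_id = character(0), icd_version = integer(0),
                        code = character(0), date = as.Date(character(0)))
  }
  check_columns(diagnoses, c("patient_id", "code", "date"), "`diagnoses`")

  aki <- exclude_aki(labs, aki_window_days)
  log_aki <- mutate(aki$excluded, stage = "aki_exclusion", .before = "reason")

  eskd_labels <- assign_groups(diagnoses, eskd_codes)
  eskd_labels <- filter(eskd_labels,
                        .data$patient_id %in% unique(aki$labs$patient_id))

  eskd <- select_eskd(aki$labs, eskd_labels, min_pre_diagnosis)
  log_eskd <- mutate(eskd$excluded, stage = "eskd_selection",
                     .before = "reason")

  normal <- select_normal(aki$labs, diagnoses, eskd_labels$patient_id,
                          ckd_exclusion_codes, min_measurements)
  log_normal <- mutate(normal$excluded, stage = "normal_selection",
                       .before = "reason")

  groups <- bind_rows(
    tibble(patient_id = normal$patient_ids,
           group = rep("normal", length(normal$patient_ids)),
           diagnosis_date = as.Date(NA)),
    tibble(patient_id = eskd$patients$patient_id, group = "eskd",
           diagnosis_date = eskd$patients$diagnosis_date)
  )
  patients <- demographics |>
    inner_join(groups, by = "patient_id") |>
    as_tibble()
  cohort_labs <- aki$labs |>
    inner_join(select(groups, "patient_id", "group"), by = "patient_id") |>
    as_tibble()

  structure(
    list(
      labs = cohort_labs,
      patients = patients,
      exclusion_log = bind_rows(log_aki, log_eskd, log_normal),
      params = list(eskd_codes = eskd_codes,
                    ckd_exclusion_codes = ckd_exclusion_codes,
                    min_measurements = min_measurements,
                    min_pre_diagnosis = min_pre_diagnosis,
                    aki_window_days = aki_window_days)
    ),
    class = "gfr_cohort"
  )
}

#' @export
print.gfr_cohort <- function(x, ...) {
  n_normal <- sum(x$patients$group == "normal")
  n_eskd <- sum(x$patients$group == "eskd")
  cat("Labeled eGFR cohort\n")
  cat(sprintf("  Normal Group: %s patients\n", format(n_normal, big.mark = ",")))
  cat(sprintf("  ESKD Group:   %s patients\n", format(n_eskd, big.mark = ",")))
  cat(sprintf("  observations: %s\n", format(nrow(x$labs), big.mark = ",")))
  if (nrow(x$exclusion_log)) {
    cat("  exclusions:\n")
    tab <- x$exclusion_log |> count(.data$stage, .data$reason)
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("    %-18s %-28s %d\n", tab$stage[i], tab$reason[i], tab$n[i]))
    }
  }
  invisible(x)
}

#' Lab rows of one group of a cohort
#'
#' Convenience accessor: the retained observations of the Normal or ESKD
#' group, optionally restricted to pre-diagnosis rows for ESKD patients
#' (the rows the CUSUM is scored on).
#'
#' @param cohort A `gfr_cohort`.
#' @param group `"normal"` or `"eskd"`.
#' @param pre_diagnosis_only For the ESKD group, keep only observations
#'   strictly before the diagnosis date (default `TRUE` there).
#' @return Tibble of lab rows.
#' @export
cohort_labs <- function(cohort, group = c("normal", "eskd"),
                        pre_diagnosis_only = group == "eskd") {
  group <- match.arg(group)
  out <- filter(cohort$labs, .data$group == !!group)
  if (group == "eskd" && isTRUE(pre_diagnosis_only)) {
    out <- out |>
      inner_join(select(cohort$patients, "patient_id", "diagnosis_date"),
                 by = "patient_id") |>
      filter(.data$date < .data$diagnosis_date) |>
      select(-"diagnosis_date")
  }
  out
}
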