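# Delimited-text readers/writers and the end-to-end pipeline. All dates are
# ISO-8601; eGFR and CUSUM values are written to 2 decimals, full precision
# is kept internally.

#' Read a longitudinal lab table
#'
#' CSV with header `patient_id,date,scr_mg_dl` (a `scr` column is also
#' accepted). Dates are parsed as ISO-8601; rows with an unparseable date
#' or a missing/non-positive creatinine are skipped with a warning
#' reporting the count.
#'
#' @param path CSV file path.
#' @return Tibble `patient_id`, `date`, `scr`, sorted per patient.
#' @export
read_labs <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  if (!"scr" %in% names(df) && "scr_mg_dl" %in% names(df)) {
    df <- rename(df, scr = "scr_mg_dl")
  }
  check_columns(df, c("patient_id", "date", "scr"), sprintf("`%s`", path))
  if (!nrow(df)) {
    warning(sprintf("%s: empty lab file", path), call. = FALSE)
    return(tibble(patient_id = character(0), date = as.Date(character(0)),
                  scr = numeric(0)))
  }
  parsed <- df |>
    mutate(date = suppressWarnings(as.Date(.data$date, format = "%Y-%m-%d")),
           scr = suppressWarnings(as.numeric(.data$scr)))
  bad <- is.na(parsed$date) | is.na(parsed$scr) | parsed$scr <= 0
  if (any(bad)) {
    warning(sprintf("%s: skipped %d malformed row(s)", path, sum(bad)),
            call. = FALSE)
  }
  parsed |>
    filter(!bad) |>
    select("patient_id", "date", "scr") |>
    arrange(.data$patient_id, .data$date)
}

#' Read a demographics table
#'
#' CSV with `patient_id`, `sex`, `birth_date` plus any subgroup flag
#' columns (`TRUE`/`FALSE` parsed as logical).
#'
#' @param path CSV file path.
#' @return Tibble, one row per patient.
#' @export
read_demographics <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    patient_id = "c", sex = "c", birth_date = readr::col_date(),
    .default = readr::col_guess()))
  check_columns(df, c("patient_id", "sex", "birth_date"),
                sprintf("`%s`", path))
  df
}

#' Read a diagnosis table
#'
#' CSV with `patient_id`, `icd_version`, `code`, `date`.
#'
#' @param path CSV file path.
#' @return Tibble of dated diagnosis codes.
#' @export
read_diagnoses <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    patient_id = "c", icd_version = "i", code = "c",
    date = readr::col_date()))
  check_columns(df, c("patient_id", "icd_version", "code", "date"),
                sprintf("`%s`", path))
  df
}

#' Write the three cohort input tables of a simulated cohort
#'
#' Emits `labs.csv`, `demographics.csv`, `diagnoses.csv` and
#' `truth.csv` under `dir`, in the schemas the readers above consume.
#'
#' @param sim A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths.
#' @export
write_sim_cohort <- function(sim, dir) {
  if (!inherits(sim, "sim_cohort")) abort_input("`sim` must be a sim_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("labs.csv", "demographics.csv",
                            "diagnoses.csv", "truth.csv"))
  readr::write_csv(rename(sim$labs, scr_mg_dl = "scr"), paths[1])
  readr::write_csv(sim$demographics, paths[2])
  readr::write_csv(sim$diagnoses, paths[3])
  readr::write_csv(sim$truth, paths[4])
  invisible(paths)
}

#' Export a CUSUM trace as CSV
#'
#' One row per observation: patient, date, eGFR (2 decimals), CUSUM value
#' (2 decimals) and the first-crossing flag.
#'
#' @param trace A `cusum_trace` from [run_cusum()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(trace, path) {
  trace |>
    mutate(egfr = round(.data$egfr, 2), cusum = round(.data$cusum, 2)) |>
    select("patient_id", "date", "egfr", "cusum", "signal") |>
    readr::write_csv(path)
  invisible(path)
}

#' Read and validate a pipeline run configuration
#'
#' YAML file of run settings. Unknown keys are rejected with a clear
#' error; unspecified keys fall back to package defaults.
#'
#' Recognized keys: `labs`, `demographics`, `diagnoses` (input paths, or
#' `simulate: {...}` with [sim_config()] fields instead), `eskd_codes`,
#' `ckd_exclusion_codes`, `min_measurements`, `min_pre_diagnosis`,
#' `aki_window_days`, `w_grid`, `t_grid`, `k`, `seed`, `w`, `threshold`,
#' `refit_reference`, `out_dir`.
#'
#' @param path YAML file path.
#' @return Named list of validated settings.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("labs", "demographics", "diagnoses", "simulate",
               "eskd_codes", "ckd_exclusion_codes", "min_measurements",
               "min_pre_diagnosis", "aki_window_days", "w_grid", "t_grid",
               "k", "seed", "w", "threshold", "refit_reference", "out_dir")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    abort_input("unknown config key(s): %s", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$simulate) &&
      !all(c("labs", "demographics", "diagnoses") %in% names(cfg))) {
    abort_input("config must give `labs`, `demographics` and `diagnoses` paths, or a `simulate` block")
  }
  if (!is.null(cfg$t_grid) && !length(cfg$t_grid)) {
    abort_input("`t_grid` must be non-empty")
  }
  cfg
}

#' Run the full pipeline: selection, reference, tuning, evaluation
#'
#' Sequences the whole analysis: read (or simulate) the input tables,
#' apply the selection criteria, estimate the normal reference, tune
#' (w, T) by cross-validation, score the cohort at the optimum, and write
#' the exclusion log, tuning grid, per-patient signal records, ROC points
#' and a plain-text summary under `out_dir`. Deterministic under a fixed
#' `seed`.
#'
#' @param config A list from [read_run_config()] (or built directly).
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, a list with the cohort, reference, tuning result,
#'   evaluation and earliness summary.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir %||% ".") {
  if (!is.null(config$t_grid) && !length(config$t_grid)) {
    abort_input("`t_grid` must be non-empty")
  }
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(config$seed) && is.null(sim_args$seed)) {
      sim_args$seed <- config$seed
    }
    sim <- simulate_cohort(do.call(sim_config, sim_args))
    labs <- sim$labs; demographics <- sim$demographics
    diagnoses <- sim$diagnoses
  } else {
    labs <- read_labs(config$labs)
    demographics <- read_demographics(config$demographics)
    diagnoses <- read_diagnoses(config$diagnoses)
  }
  cohort <- build_cohort(
    labs, demographics, diagnoses,
    eskd_codes = config$eskd_codes %||% c("585.6", "N18.6"),
    ckd_exclusion_codes = config$ckd_exclusion_codes %||%
      c("585*", "586", "N18*", "N19"),
    min_measurements = config$min_measurements %||% 9,
    min_pre_diagnosis = config$min_pre_diagnosis %||% 2,
    aki_window_days = config$aki_window_days %||% 92)
  ref <- estimate_reference(cohort_labs(cohort, "normal"))
  tuning <- kfold_tune(
    cohort,
    w_grid = config$w_grid %||% c(0.25, 0.5, 0.75, 1, 1.25),
    t_grid = config$t_grid %||% c(-2, -3, -4, -5, -6),
    k = config$k %||% 10, seed = config$seed %||% 1L,
    refit_reference = config$refit_reference %||% TRUE, ref = ref)
  w_star <- config[["w"]] %||% tuning$best$w
  t_star <- config[["threshold"]] %||% tuning$best$threshold
  eval <- classify_cohort(cohort, ref, w_star, t_star)
  roc <- roc_curve(cohort, ref, w_star)
  early <- tryCatch(earliness_summary(eval), error = function(e) NULL)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$exclusion_log, file.path(out_dir, "exclusion_log.csv"))
  readr::write_csv(tuning$grid, file.path(out_dir, "tuning_grid.csv"))
  readr::write_csv(
    mutate(eval$signals,
           egfr_at_signal = round(.data$egfr_at_signal, 2)),
    file.path(out_dir, "signals.csv"))
  readr::write_csv(as_tibble(roc), file.path(out_dir, "roc.csv"))

  report <- c(
    "CUSUM-GFR pipeline report",
    sprintf("Normal Group: %d patients; ESKD Group: %d patients",
            sum(cohort$patients$group == "normal"),
            sum(cohort$patients$group == "eskd")),
    sprintf("Reference: mean %.2f (se %.3g), pooled SD %.3f",
            ref$overall_mean, ref$overall_se, ref$sigma),
    sprintf("Best (w, T) = (%g, %g); CV accuracy %.3f, sensitivity %.3f, specificity %.3f",
            tuning$best$w, tuning$best$threshold, tuning$best$accuracy,
            tuning$best$sensitivity, tuning$best$specificity),
    sprintf("ROC AUC at w = %g: %.3f", w_star, roc_auc(roc)),
    if (!is.null(early)) {
      sprintf("Earliness: mean %.0f d (se %.0f), median %.0f d; signaled at eGFR >= 30/45/60: %.1f%% / %.1f%% / %.1f%%",
              early$mean_earliness, early$se_earliness,
              early$median_earliness, early$pct_egfr_ge_30,
              early$pct_egfr_ge_45, early$pct_egfr_ge_60)
    } else "Earliness: no true positives signaled before diagnosis"
  )
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(list(cohort = cohort, reference = ref, tuning = tuning,
                 evaluation = eval, roc = roc, earliness = early))
}
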