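#' Score a labeled cohort at a given (w, T)
#'
#' Runs the CUSUM over every retained patient and classifies each one. For
#' ESKD patients only pre-diagnosis observations are scored, so a true
#' positive is by construction a signal strictly before the diagnosis
#' date; an ESKD patient who never crosses the threshold before diagnosis
#' is a false negative. Normal-Group patients who signal are false
#' positives.
#'
#' @param cohort A [gfr_cohort][build_cohort].
#' @param ref A [gfr_reference][estimate_reference].
#' @param w Allowance, >= 0.
#' @param threshold Signal threshold `T`, <= 0.
#' @return A `cusum_eval` object: list with `signals` (one row per patient:
#'   `group`, `signaled`, `signal_date`, `egfr_at_signal`, `diagnosis_date`,
#'   `earliness`, `pre_diagnosis`, `outcome` in tp/fp/tn/fn), `counts`
#'   (tp/fp/tn/fn) and the parameters. `glance()` gives the performance
#'   metrics, `tidy()` the per-patient records.
#' @export
classify_cohort <- function(cohort, ref, w = 0.75, threshold = -4) {
  if (!inherits(cohort, "gfr_cohort")) abort_input("`cohort` must be a gfr_cohort")
  if (!nrow(cohort$patients)) {
    return(structure(
      list(signals = tibble(), counts = tibble(tp = 0L, fp = 0L, tn = 0L, fn = 0L),
           w = w, threshold = threshold),
      class = "cusum_eval"))
  }
  scored <- bind_rows(cohort_labs(cohort, "normal"),
                      cohort_labs(cohort, "eskd"))
  trace <- run_cusum(scored, ref, w, threshold)
  signals <- signal_summary(trace, threshold) |>
    inner_join(select(cohort$patients, "patient_id", "group", "diagnosis_date"),
               by = "patient_id") |>
    mutate(
      earliness = ifelse(
        .data$group == "eskd" & .data$signaled,
        earliness_days(.data$signal_date, .data$diagnosis_date), NA_integer_),
      pre_diagnosis = !is.na(.data$earliness) & .data$earliness > 0,
      outcome = case_when(
        .data$group == "eskd" & .data$signaled ~ "tp",
        .data$group == "eskd" ~ "fn",
        .data$signaled ~ "fp",
        TRUE ~ "tn")
    )
  counts <- tibble(
    tp = sum(signals$outcome == "tp"), fp = sum(signals$outcome == "fp"),
    tn = sum(signals$outcome == "tn"), fn = sum(signals$outcome == "fn"))
  structure(list(signals = signals, counts = counts, w = w,
                 threshold = threshold),
            class = "cusum_eval")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sensitivity = tp/(tp+fn)`, `specificity = tn/(tn+fp)`,
#' `accuracy = (tp+tn)/total`, plus Youden's J. An empty class (no ESKD
#' patients, or no Normal patients) makes a metric undefined and raises an
#' error rather than returning a silent zero.
#'
#' @param counts Data frame (or one-row tibble) with columns `tp`, `fp`,
#'   `tn`, `fn`; a `cusum_eval` is also accepted.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`, `youden`.
#' @export
confusion_metrics <- function(counts) {
  if (inherits(counts, "cusum_eval")) counts <- counts$counts
  check_columns(counts, c("tp", "fp", "tn", "fn"), "`counts`")
  tp <- sum(counts$tp); fp <- sum(counts$fp)
  tn <- sum(counts$tn); fn <- sum(counts$fn)
  if (any(c(tp, fp, tn, fn) < 0)) abort_input("counts must be non-negative")
  if (tp + fn == 0 || tn + fp == 0) {
    abort_input(
      "undefined metric: need at least one patient in each class (tp+fn = %d, tn+fp = %d)",
      tp + fn, tn + fp)
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = sens, specificity = spec,
         accuracy = (tp + tn) / (tp + fp + tn + fn),
         youden = sens + spec - 1)
}

#' @export
print.cusum_eval <- function(x, ...) {
  cat(sprintf("CUSUM-GFR evaluation at w = %g, T = %g\n", x$w, x$threshold))
  cat(sprintf("  tp %d  fp %d  tn %d  fn %d\n",
              x$counts$tp, x$counts$fp, x$counts$tn, x$counts$fn))
  m <- try(confusion_metrics(x$counts), silent = TRUE)
  if (!inherits(m, "try-error")) {
    cat(sprintf("  sensitivity %.3f  specificity %.3f  accuracy %.3f\n",
                m$sensitivity, m$specificity, m$accuracy))
  }
  invisible(x)
}

#' @rdname classify_cohort
#' @param x,... broom-method arguments.
#' @method tidy cusum_eval
#' @export
tidy.cusum_eval <- function(x, ...) x$signals

#' @rdname classify_cohort
#' @method glance cusum_eval
#' @export
glance.cusum_eval <- function(x, ...) {
  bind_cols(confusion_metrics(x$counts), tibble(w = x$w, threshold = x$threshold))
}

#' Earliness and eGFR-at-signal summary of true positives
#'
#' Summarizes how far ahead of the ESKD diagnosis the signal came, over the
#' patients correctly identified before their diagnosis: mean earliness
#' with its standard error (SD/sqrt(n)), median earliness, and the
#' percentage of signals occurring while eGFR was still at or above 30, 45
#' and 60 mL/min/1.73 m^2.
#'
#' @param signals A `cusum_eval` or its `signals` tibble.
#' @return One-row tibble: `n`, `mean_earliness`, `se_earliness`,
#'   `median_earliness` (days), `pct_egfr_ge_30/45/60` (percent).
#' @export
earliness_summary <- function(signals) {
  if (inherits(signals, "cusum_eval")) signals <- signals$signals
  check_columns(signals, c("outcome", "earliness", "egfr_at_signal"),
                "`signals`")
  tp <- filter(signals, .data$outcome == "tp", .data$earliness > 0)
  if (!nrow(tp)) {
    abort_input("no true positives signaling before diagnosis")
  }
  tibble(
    n = nrow(tp),
    mean_earliness = mean(tp$earliness),
    se_earliness = sd(tp$earliness) / sqrt(nrow(tp)),
    median_earliness = median(tp$earliness),
    pct_egfr_ge_30 = 100 * mean(tp$egfr_at_signal >= 30),
    pct_egfr_ge_45 = 100 * mean(tp$egfr_at_signal >= 45),
    pct_egfr_ge_60 = 100 * mean(tp$egfr_at_signal >= 60)
  )
}

#' Performance and earliness stratified by a patient subgroup
#'
#' Splits the cohort by a demographic or clinical stratifier, reports
#' per-level confusion metrics (flagged undefined when a level lacks one of
#' the classes rather than erroring) and mean earliness, and compares
#' earliness between each level and the rest with a Welch two-sample test.
#'
#' @param cohort The `gfr_cohort` the evaluation was run on.
#' @param eval A `cusum_eval` from [classify_cohort()].
#' @param stratifier Name of a column of `cohort$patients` (e.g. `"sex"`,
#'   `"race"`, `"hypertension"`, `"diabetes"`, `"cardiovascular"`,
#'   `"hypercholesterolemia"`, `"smoking"`), or `"age_band"` for under/over
#'   65 at first measurement.
#' @return Tibble with one row per level: `level`, `n`, confusion counts,
#'   `sensitivity`/`specificity`/`accuracy` (NA when undefined), `defined`,
#'   `mean_earliness`, and the Welch comparison of earliness against the
#'   other levels (`earliness_diff`, `earliness_p`).
#' @export
subgroup_performance <- function(cohort, eval, stratifier) {
  if (!inherits(eval, "cusum_eval")) abort_input("`eval` must be a cusum_eval")
  pts <- cohort$patients
  if (identical(stratifier, "age_band")) {
    first_age <- cohort$labs |>
      group_by(.data$patient_id) |>
      summarise(first_age = min(.data$age), .groups = "drop")
    pts <- pts |>
      inner_join(first_age, by = "patient_id") |>
      mutate(age_band = ifelse(.data$first_age >= 65, "65_and_over", "under_65"))
  } else if (!stratifier %in% names(pts)) {
    abort_input("`stratifier` must be \"age_band\" or a column of cohort$patients")
  }
  dat <- eval$signals |>
    inner_join(pts[c("patient_id", stratifier)], by = "patient_id") |>
    rename(level = !!stratifier) |>
    mutate(level = as.character(.data$level))
  levels <- sort(unique(dat$level))
  rows <- map(levels, function(lv) {
    sub <- filter(dat, .data$level == lv)
    counts <- tibble(tp = sum(sub$outcome == "tp"), fp = sum(sub$outcome == "fp"),
                     tn = sum(sub$outcome == "tn"), fn = sum(sub$outcome == "fn"))
    defined <- (counts$tp + counts$fn) > 0 && (counts$tn + counts$fp) > 0
    m <- if (defined) confusion_metrics(counts) else
      bind_cols(counts, tibble(sensitivity = NA_real_, specificity = NA_real_,
                               accuracy = NA_real_, youden = NA_real_))
    e_in <- sub$earliness[sub$outcome == "tp" & sub$earliness > 0]
    e_out <- dat$earliness[dat$level != lv & dat$outcome == "tp" &
                             dat$earliness > 0]
    welch <- if (length(e_in) >= 2 && length(e_out) >= 2) {
      tryCatch({
        tt <- t.test(e_in, e_out)
        c(diff = unname(tt$estimate[1] - tt$estimate[2]), p = tt$p.value)
      }, error = function(e) {
        # degenerate spread (constant earliness); report the point estimate
        c(diff = mean(e_in) - mean(e_out), p = NA_real_)
      })
    } else c(diff = NA_real_, p = NA_real_)
    bind_cols(
      tibble(level = lv, n = nrow(sub)), m,
      tibble(defined = defined,
             mean_earliness = if (length(e_in)) mean(e_in) else NA_real_,
             earliness_diff = welch[["diff"]], earliness_p = welch[["p"]]))
  })
  list_rbind(rows)
}
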