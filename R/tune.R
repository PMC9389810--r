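# (w, T) tuning by stratified k-fold cross-validation, and ROC construction.
# The expensive part -- the CUSUM trace -- depends on w but not on T, so each
# fold computes one running-minimum per patient per w and then sweeps the
# whole T grid over those minima.

# per-patient running minimum of the CUSUM at a given w (threshold-free)
min_cusum_by_patient <- function(labs, ref, w) {
  run_cusum(labs, ref, w = w, threshold = 0) |>
    group_by(.data$patient_id) |>
    summarise(min_cusum = min(.data$cusum), .groups = "drop")
}

# scored labs: normal rows plus pre-diagnosis ESKD rows
scored_labs <- function(cohort) {
  bind_rows(cohort_labs(cohort, "normal"), cohort_labs(cohort, "eskd"))
}

# sweep a T grid over per-patient minima -> one metrics row per (w, T)
sweep_thresholds <- function(minima, groups, w, t_grid) {
  dat <- inner_join(minima, groups, by = "patient_id")
  map_dfr(t_grid, function(tt) {
    signaled <- dat$min_cusum <= tt
    counts <- tibble(
      tp = sum(signaled & dat$group == "eskd"),
      fn = sum(!signaled & dat$group == "eskd"),
      fp = sum(signaled & dat$group == "normal"),
      tn = sum(!signaled & dat$group == "normal"))
    bind_cols(tibble(w = w, threshold = tt), confusion_metrics(counts))
  })
}

#' Tune (w, T) by stratified k-fold cross-validation
#'
#' Splits patients into `k` folds stratified by group label (each fold
#' contains both Normal and ESKD patients), and for every (w, T) grid point
#' averages the test-fold sensitivity, specificity and accuracy. By default
#' the normal reference is re-estimated from each fold's training Normal
#' patients, so test patients are never scored against a reference they
#' contributed to; pass `refit_reference = FALSE` with a fixed `ref` to
#' score everyone against a single global reference instead.
#'
#' The chosen optimum maximizes mean accuracy, with ties broken by Youden's
#' J (sensitivity + specificity - 1) and then by the more negative
#' threshold.
#'
#' @param cohort A `gfr_cohort` with both groups of size >= `k`.
#' @param w_grid,t_grid Numeric grids; defaults bracket the clinically
#'   useful region (`w` 0.25--1.25, `T` -6 to -2).
#' @param k Number of folds, default 10.
#' @param seed Integer seed fixing the fold assignment (and hence the whole
#'   result).
#' @param refit_reference Re-estimate the reference inside each training
#'   fold (default `TRUE`).
#' @param ref A `gfr_reference`, required when `refit_reference = FALSE`.
#' @return A `cusum_tuning` object: `grid` (mean cross-validated metrics
#'   per (w, T)), `best` (one row), `fold_metrics`, `k`, `seed`. `tidy()`
#'   returns the grid, `glance()` the best row, `autoplot()` an accuracy
#'   heat map.
#' @export
kfold_tune <- function(cohort,
                       w_grid = c(0.25, 0.5, 0.75, 1, 1.25),
                       t_grid = c(-2, -3, -4, -5, -6),
                       k = 10, seed = 1L, refit_reference = TRUE, ref = NULL) {
  if (!length(w_grid) || !length(t_grid)) {
    abort_input("`w_grid` and `t_grid` must be non-empty")
  }
  if (k < 2) abort_input("`k` must be >= 2")
  if (!refit_reference && is.null(ref)) {
    abort_input("`ref` is required when refit_reference = FALSE")
  }
  pts <- cohort$patients
  n_by_group <- table(pts$group)
  if (length(n_by_group) < 2 || any(n_by_group < k)) {
    abort_input("both groups must have at least k = %d patients", k)
  }
  folds <- withr::with_seed(seed, {
    pts |>
      group_by(.data$group) |>
      mutate(fold = sample(rep_len(seq_len(k), n()))) |>
      ungroup() |>
      select("patient_id", "group", "fold")
  })
  labs_all <- scored_labs(cohort)
  normal_labs <- cohort_labs(cohort, "normal")

  fold_metrics <- map_dfr(seq_len(k), function(f) {
    test_ids <- folds$patient_id[folds$fold == f]
    ref_f <- if (refit_reference) {
      train_normal <- folds$patient_id[folds$fold != f &
                                         folds$group == "normal"]
      estimate_reference(
        filter(normal_labs, .data$patient_id %in% train_normal),
        decline_rate = if (is.null(ref)) 0.81 else ref$decline_rate)
    } else ref
    test_labs <- filter(labs_all, .data$patient_id %in% test_ids)
    test_groups <- folds |>
      filter(.data$fold == f) |>
      select("patient_id", "group")
    map_dfr(w_grid, function(w) {
      minima <- min_cusum_by_patient(test_labs, ref_f, w)
      sweep_thresholds(minima, test_groups, w, t_grid)
    }) |> mutate(fold = f)
  })

  grid <- fold_metrics |>
    group_by(.data$w, .data$threshold) |>
    summarise(across(c("sensitivity", "specificity", "accuracy"), mean),
              .groups = "drop") |>
    mutate(youden = .data$sensitivity + .data$specificity - 1)
  best <- grid |>
    arrange(desc(.data$accuracy), desc(.data$youden), .data$threshold) |>
    slice(1)
  structure(
    list(grid = grid, best = best, fold_metrics = fold_metrics,
         k = k, seed = seed, refit_reference = refit_reference),
    class = "cusum_tuning")
}

#' @export
print.cusum_tuning <- function(x, ...) {
  cat(sprintf("CUSUM-GFR tuning: %d-fold CV over %d grid points (seed %d)\n",
              x$k, nrow(x$grid), x$seed))
  cat(sprintf(
    "  best: w = %g, T = %g  (accuracy %.3f, sensitivity %.3f, specificity %.3f)\n",
    x$best$w, x$best$threshold, x$best$accuracy, x$best$sensitivity,
    x$best$specificity))
  invisible(x)
}

#' @rdname kfold_tune
#' @param x,... broom-method arguments.
#' @method tidy cusum_tuning
#' @export
tidy.cusum_tuning <- function(x, ...) x$grid

#' @rdname kfold_tune
#' @method glance cusum_tuning
#' @export
glance.cusum_tuning <- function(x, ...) {
  bind_cols(x$best, tibble(k = x$k, seed = x$seed))
}

#' ROC curve over a threshold grid at fixed w
#'
#' Scores the whole cohort once per `w` and sweeps the threshold grid to
#' trace out (1 - specificity, sensitivity) operating points. As `T`
#' rises toward 0 signalling becomes easier, so sensitivity is
#' non-decreasing and specificity non-increasing along the grid. The AUC is
#' the trapezoid area after anchoring the curve at (0, 0) and (1, 1).
#'
#' @param cohort A `gfr_cohort`.
#' @param ref A `gfr_reference`.
#' @param w Allowance, fixed along the curve.
#' @param t_grid Thresholds; default a dense grid from -10 to 0.
#' @return A `cusum_roc` tibble (`threshold`, `sensitivity`, `specificity`,
#'   `fpr`) sorted by threshold, with the AUC in `attr(, "auc")`.
#' @export
roc_curve <- function(cohort, ref, w = 0.75, t_grid = seq(-10, 0, by = 0.25)) {
  if (is.unsorted(t_grid)) t_grid <- sort(t_grid)
  groups <- select(cohort$patients, "patient_id", "group")
  minima <- min_cusum_by_patient(scored_labs(cohort), ref, w)
  pts <- sweep_thresholds(minima, groups, w, t_grid) |>
    mutate(fpr = 1 - .data$specificity) |>
    select("threshold", "sensitivity", "specificity", "fpr")
  curve <- unique(rbind(
    data.frame(fpr = 0, sensitivity = 0),
    pts[order(pts$fpr, pts$sensitivity), c("fpr", "sensitivity")],
    data.frame(fpr = 1, sensitivity = 1)))
  auc <- sum(diff(curve$fpr) *
               (head(curve$sensitivity, -1) + curve$sensitivity[-1]) / 2)
  out <- as_tibble(pts)
  attr(out, "auc") <- auc
  attr(out, "w") <- w
  class(out) <- c("cusum_roc", class(out))
  out
}

#' Area under a ROC curve
#'
#' @param roc A `cusum_roc` from [roc_curve()].
#' @return The trapezoid AUC in `[0, 1]`.
#' @export
roc_auc <- function(roc) {
  auc <- attr(roc, "auc")
  if (is.null(auc)) abort_input("`roc` must come from roc_curve()")
  auc
}
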