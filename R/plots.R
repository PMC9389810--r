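# ggplot2 methods for the result types

#' Plot CUSUM traces
#'
#' One panel per patient: the CUSUM statistic over time with the signal
#' threshold and the first crossing marked.
#'
#' @param object A `cusum_trace` from [run_cusum()].
#' @param patients Optional character vector of patient ids to show
#'   (default: up to 12).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cusum_trace
#' @export
autoplot.cusum_trace <- function(object, patients = NULL, ...) {
  thr <- attr(object, "threshold")
  if (is.null(patients)) {
    patients <- head(unique(object$patient_id), 12)
  }
  dat <- filter(object, .data$patient_id %in% patients)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$date, y = .data$cusum)) +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = filter(dat, .data$signal),
                        colour = "firebrick", size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$patient_id), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "CUSUM-GFR",
                  title = sprintf("CUSUM-GFR traces (w = %g, T = %g)",
                                  attr(object, "w"), thr))
}

#' Plot a ROC curve
#'
#' @param object A `cusum_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cusum_roc
#' @export
autoplot.cusum_roc <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC at w = %g (AUC %.3f)",
                                  attr(object, "w"), roc_auc(object)))
}

#' Plot a tuning grid
#'
#' Heat map of cross-validated accuracy over the (w, T) grid with the
#' chosen optimum marked.
#'
#' @param object A `cusum_tuning` from [kfold_tune()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cusum_tuning
#' @export
autoplot.cusum_tuning <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = factor(.data$w),
                               y = factor(.data$threshold),
                               fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = object$best, shape = 8, size = 3) +
    ggplot2::labs(x = "w (allowance)", y = "T (threshold)",
                  fill = "CV accuracy",
                  title = sprintf("%d-fold CV accuracy; best (w, T) = (%g, %g)",
                                  object$k, object$best$w,
                                  object$best$threshold))
}
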