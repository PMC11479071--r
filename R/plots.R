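#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a vital signal
#'
#' The band-passed vital signal over time, optionally with detected peaks.
#'
#' @param object a `vital_signal` from [select_mp()].
#' @param peaks optional [detect_peaks()] `peak_set` to overlay.
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.vital_signal <- function(object, peaks = NULL, ...) {
  df <- tibble::tibble(
    time_s = object$t0 + (seq_along(object$v0) - 1L) / object$fps,
    amplitude = object$v0)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "vital signal",
                  title = sprintf("Vital signal, bin %d", object$mp_bin))
  if (!is.null(peaks)) {
    pk <- tibble::tibble(time_s = peaks$times_s, amplitude = peaks$amplitudes)
    p <- p + ggplot2::geom_point(data = pk, colour = "red", size = 1)
  }
  p
}

#' Plot an RR-interval tachogram
#'
#' @param object an `rr_series` from [build_rr()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.rr_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$start_s, .data$interval_ms)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "RR interval (ms)",
                  title = "RR tachogram")
}

#' Plot a movement mask
#'
#' Per-second movement scores with the CFAR threshold and flagged seconds.
#'
#' @param object a `movement_mask` from [detect_movement()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.movement_mask <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$second, .data$score,
                                       colour = .data$flagged)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "red")) +
    ggplot2::labs(x = "second", y = "movement score",
                  title = sprintf("Movement detection (%d s flagged)",
                                  attr(object, "total_movement_s")))
}

#' Plot a ROC curve
#'
#' @param object a `roc_result` from [roc_analysis()].
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  best <- tibble::tibble(fpr = 1 - object$specificity,
                         tpr = object$sensitivity)
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = best, ggplot2::aes(.data$fpr, .data$tpr),
                        colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC %.3f)", object$auc))
}

#' Bland-Altman plot for one index of an agreement report
#'
#' Differences (radar minus reference) against pair means, with the bias and
#' 1.96-SD limits of agreement.
#'
#' @param report an [agreement_report()].
#' @param index index name (e.g. `"rmssd"`).
#' @return a ggplot.
#' @export
plot_bland_altman <- function(report, index = "rmssd") {
  stopifnot(inherits(report, "agreement_report"))
  x <- report$records[[paste0("ref_", index)]]
  y <- report$records[[paste0("radar_", index)]]
  ba <- bland_altman(x, y)
  df <- tibble::tibble(mean = (x + y) / 2, diff = y - x)
  ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$diff)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = ba$bias, colour = "blue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = sprintf("mean of methods (%s)", index),
                  y = "radar - reference",
                  title = sprintf("Bland-Altman: %s (bias %.2f)",
                                  index, ba$bias))
}
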