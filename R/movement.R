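#' Per-second sedentary-movement score
#'
#' The movement statistic of second `s` is the mean over its frames of the
#' total squared frame-to-frame change,
#' `sum_k |frames[k, t] - frames[k, t - 1]|^2`, normalised by the median
#' score over the whole evaluation (so the score is scale-invariant). It is
#' computed on the phase-compensated cube *before* band-pass filtering, so
#' gross motion is not filtered away.
#'
#' @param cube a phase-compensated [radar_cube()], at least 2 s long.
#' @return a tibble with `second` (0-based), `score`.
#' @export
movement_statistic <- function(cube) {
  stopifnot(inherits(cube, "radar_cube"))
  n <- ncol(cube$frames)
  if (n < 2 * cube$fps) stop("cube shorter than 2 s", call. = FALSE)
  dsq <- colSums(Mod(cube$frames[, -1L, drop = FALSE] -
                     cube$frames[, -n, drop = FALSE])^2)
  sec <- floor((seq_len(n) - 1L) / cube$fps)
  n_sec <- floor(n / cube$fps)
  keep <- sec < n_sec
  score <- as.numeric(tapply(c(0, dsq)[keep], sec[keep], mean))
  med <- stats::median(score)
  if (med > 0) score <- score / med
  tibble::tibble(second = seq_len(n_sec) - 1L, score = score)
}

#' CFAR movement detection
#'
#' A constant-false-alarm-rate rule over the full evaluation's score
#' sequence: the threshold is `alpha` times the one-sided trimmed mean of the
#' scores (the largest `trim` fraction — the candidate movement seconds —
#' excluded from the mean), and a second is flagged when its score exceeds
#' the threshold. The decision is per second; the threshold is fixed per
#' evaluation.
#'
#' @param scores a numeric vector of per-second scores, or the tibble
#'   returned by [movement_statistic()].
#' @param alpha threshold multiplier.
#' @param trim fraction (in `[0, 0.5)`) of the largest scores excluded from
#'   the background mean.
#' @return a tibble of class `movement_mask` with `second`, `score`,
#'   `flagged`; attribute `total_movement_s` counts flagged seconds and
#'   attribute `threshold` records the decision level.
#' @export
detect_movement <- function(scores, alpha = 5.0, trim = 0.1) {
  if (is.data.frame(scores)) {
    second <- scores$second
    scores <- scores$score
  } else {
    second <- seq_along(scores) - 1L
  }
  if (!length(scores)) stop("`scores` is empty", call. = FALSE)
  if (trim < 0 || trim >= 0.5) stop("`trim` must be in [0, 0.5)", call. = FALSE)
  cut <- stats::quantile(scores, 1 - trim, names = FALSE, type = 7)
  bg <- mean(scores[scores <= cut])
  threshold <- alpha * bg
  flagged <- scores > threshold
  if (!any(flagged) && length(unique(scores)) == 1L && alpha <= 1)
    warning("all scores equal and alpha <= 1: nothing flagged")
  out <- tibble::tibble(second = second, score = scores, flagged = flagged)
  class(out) <- c("movement_mask", class(out))
  attr(out, "total_movement_s") <- sum(flagged)
  attr(out, "threshold") <- threshold
  out
}

#' Pad a movement mask
#'
#' Extends every flagged second by `pad_s` seconds on each side (clipped to
#' the mask range). Motion artifact spreads through a band-pass filter by its
#' group delay, so intervals adjacent to a movement burst are also
#' contaminated; [evaluate_hrv()] pads the mask by the filter transient
#' before RR exclusion.
#'
#' @param mask a [detect_movement()] mask.
#' @param pad_s non-negative number of seconds to pad on each side.
#' @return the mask with an extended `flagged` column and updated
#'   `total_movement_s` attribute.
#' @export
pad_mask <- function(mask, pad_s) {
  stopifnot(is.data.frame(mask), pad_s >= 0)
  pad_s <- as.integer(ceiling(pad_s))
  if (pad_s > 0 && any(mask$flagged)) {
    sec <- unique(unlist(lapply(mask$second[mask$flagged],
                                function(s) (s - pad_s):(s + pad_s))))
    mask$flagged <- mask$second %in% sec
  }
  attr(mask, "total_movement_s") <- sum(mask$flagged)
  mask
}

#' Flagged seconds of a movement mask
#' @param mask a [detect_movement()] result (or any tibble with `second`,
#'   `flagged`).
#' @return integer vector of flagged 0-based seconds.
#' @export
flagged_seconds <- function(mask) {
  if (is.null(mask)) return(integer(0))
  as.integer(mask$second[mask$flagged])
}
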