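#' Amplitude-ordered iterative peak detection
#'
#' Detects heartbeat peaks in amplitude order rather than chronologically.
#' A working copy `v` of the vital signal is scanned repeatedly: the global
#' argmax `x_n` and its amplitude `y_n` are recorded and `v` is zeroed on
#' `[x_n - R, x_n + R]` (clipped to the record); iteration stops when no
#' positive sample remains or the candidate count exceeds `limit`. A
#' candidate is then validated as a true peak when its amplitude attains the
#' maximum of the *original* signal over its own `±R` window (a candidate can
#' be the argmax of the suppressed copy without being a local maximum of the
#' original); validated peaks are returned in chronological order.
#'
#' The half-window `R` is the detector's resolution: two peaks closer than
#' `R + 1` frames cannot both be kept. Equal-amplitude argmax ties break to
#' the lowest index. With `strict = TRUE` validation uses a strict `>`
#' (which a candidate can never satisfy over a window containing itself, so
#' it is only useful for sensitivity checks against the `>=` reading).
#'
#' @param vital a `vital_signal` from [select_mp()], or a numeric vector
#'   (then `fps` defaults to 1 and indices are frames).
#' @param R half-window in frames, >= 1; see [default_R()].
#' @param limit maximum number of candidates examined.
#' @param strict use strict `>` validation (see Details).
#' @return a list of class `peak_set`: `indices` (0-based frame indices,
#'   strictly increasing), `amplitudes`, `times_s`, `R`, `n_candidates`,
#'   `fps`, `t0`.
#' @export
detect_peaks <- function(vital, R = NULL, limit = NULL, strict = FALSE) {
  if (inherits(vital, "vital_signal")) {
    v0 <- vital$v0; fps <- vital$fps; t0 <- vital$t0
  } else {
    v0 <- as.numeric(vital); fps <- 1; t0 <- 0
  }
  if (is.null(R)) R <- default_R(fps)
  if (is.null(limit)) limit <- ceiling(length(v0) / fps * 130 / 60)
  if (R < 1) stop("`R` must be >= 1", call. = FALSE)
  if (limit < 1) stop("`limit` must be >= 1", call. = FALSE)
  n <- length(v0)
  if (n <= 2 * R) stop("signal shorter than 2R + 1 samples", call. = FALSE)
  if (any(!is.finite(v0))) stop("non-finite samples in the vital signal", call. = FALSE)

  v <- v0
  xs <- integer(0); ys <- numeric(0)
  n_cand <- 0L
  while (n_cand < limit) {
    i <- which.max(v)
    if (v[i] <= 0) break
    n_cand <- n_cand + 1L
    xs[n_cand] <- i
    ys[n_cand] <- v[i]
    v[max(1L, i - R):min(n, i + R)] <- 0
  }
  cmp <- if (strict) `>` else `>=`
  keep <- vapply(seq_len(n_cand), function(j) {
    w <- v0[max(1L, xs[j] - R):min(n, xs[j] + R)]
    cmp(ys[j], max(w))
  }, logical(1))
  idx <- sort(xs[keep]) - 1L  # 0-based
  structure(list(indices = idx, amplitudes = v0[idx + 1L],
                 times_s = t0 + idx / fps, R = as.integer(R),
                 n_candidates = n_cand, fps = fps, t0 = t0),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks (R = %d frames, %d candidates)\n",
              length(x$indices), x$R, x$n_candidates))
  invisible(x)
}

#' Default peak-detection half-window
#'
#' Half the minimum plausible beat spacing for an adult heart-rate ceiling:
#' `floor(fps * 60 / (2 * hr_max_bpm))` frames, so that even at the fastest
#' plausible rate two successive beats stay more than `R` frames apart.
#'
#' @param fps slow-time sampling rate (Hz).
#' @param hr_max_bpm heart-rate ceiling (beats per minute).
#' @return half-window in frames (250 FPS at 130 bpm gives 57).
#' @export
default_R <- function(fps, hr_max_bpm = 130) {
  if (fps <= 0) stop("`fps` must be positive", call. = FALSE)
  floor(fps * 60 / (2 * hr_max_bpm))
}
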