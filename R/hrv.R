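#' Spectral configuration for frequency-domain HRV
#'
#' The RR sequence is mean-removed, tapered by a Hamming window of its own
#' length, zero-padded to `fft_size` and transformed; power is the squared
#' magnitude. The beat-indexed spectrum is mapped to Hz through the effective
#' sampling rate `1000 / mean RR` beats per second (no interpolation or
#' resampling of the RR series). Band edges are half-open `[lo, hi)`, so
#' 0.15 Hz belongs to HF only.
#'
#' @param fft_size transform length, a power of two.
#' @param lf_band,hf_band low/high-frequency band edges in Hz.
#' @param mode `"power"` (squared magnitude, default) or `"magnitude"` for
#'   sensitivity checks.
#' @return a list of class `spectral_config`.
#' @export
spectral_config <- function(fft_size = 2^18, lf_band = c(0.05, 0.15),
                            hf_band = c(0.15, 0.40),
                            mode = c("power", "magnitude")) {
  if (bitwAnd(fft_size, fft_size - 1L) != 0)
    stop("`fft_size` must be a power of two", call. = FALSE)
  if (lf_band[2] > hf_band[1])
    stop("LF and HF bands must be disjoint", call. = FALSE)
  structure(list(fft_size = as.integer(fft_size), lf_band = lf_band,
                 hf_band = hf_band, mode = match.arg(mode)),
            class = "spectral_config")
}

#' Build an RR-interval series with movement exclusion
#'
#' Successive peak (or beat) timestamps become RR intervals in milliseconds.
#' Any interval whose `[start, end]` time span intersects a flagged movement
#' second `[s, s + 1)` is dropped; the surviving intervals are concatenated
#' without interpolation (the RR sequence is treated as continuous). The same
#' code path serves the radar peaks and the reference beat times, so the two
#' methods are processed identically.
#'
#' @param x a [detect_peaks()] `peak_set`, or a numeric vector of beat times
#'   in seconds (strictly increasing).
#' @param mask a [detect_movement()] mask, or `NULL` for no exclusion.
#' @param fps frames per second; only used when `x` is a vector of frame
#'   indices rather than seconds (not needed for a `peak_set`).
#' @return a tibble of class `rr_series` with `interval_ms`, `start_s`,
#'   `end_s`; attribute `n_excluded_movement` counts dropped intervals.
#' @export
build_rr <- function(x, mask = NULL, fps = NULL) {
  if (inherits(x, "peak_set")) {
    times <- x$times_s
  } else if (is.numeric(x)) {
    times <- if (is.null(fps)) as.numeric(x) else as.numeric(x) / fps
  } else stop("`x` must be a peak_set or numeric beat times", call. = FALSE)
  if (length(times) < 2L) stop("need at least 2 peaks", call. = FALSE)
  if (any(diff(times) <= 0)) stop("beat times must be strictly increasing", call. = FALSE)
  start_s <- times[-length(times)]
  end_s <- times[-1L]
  flag <- flagged_seconds(mask)
  drop <- rep(FALSE, length(start_s))
  if (length(flag)) {
    # interval [start, end] intersects flagged second [s, s+1)
    drop <- vapply(seq_along(start_s), function(i)
      any(end_s[i] > flag & start_s[i] < flag + 1), logical(1))
  }
  out <- tibble::tibble(interval_ms = (end_s - start_s)[!drop] * 1000,
                        start_s = start_s[!drop], end_s = end_s[!drop])
  class(out) <- c("rr_series", class(out))
  attr(out, "n_excluded_movement") <- sum(drop)
  out
}

#' Time-domain HRV indices
#'
#' Mean RR (arithmetic mean), SDNN (sample standard deviation, n-1
#' denominator by convention of HRV toolkits; `population = TRUE` switches to
#' the n denominator) and RMSSD (root mean square of successive differences).
#'
#' @param rr an [build_rr()] `rr_series` or numeric vector of intervals (ms).
#' @param population use the population (n) denominator for SDNN.
#' @return named list `mean_rr_ms`, `sdnn_ms`, `rmssd_ms`.
#' @export
time_domain <- function(rr, population = FALSE) {
  iv <- rr_intervals(rr)
  if (length(iv) < 2L) stop("need at least 2 intervals", call. = FALSE)
  sdnn <- stats::sd(iv)
  if (population) sdnn <- sdnn * sqrt((length(iv) - 1) / length(iv))
  rmssd <- if (length(iv) >= 3L) sqrt(mean(diff(iv)^2)) else NA_real_
  list(mean_rr_ms = mean(iv), sdnn_ms = sdnn, rmssd_ms = rmssd)
}

rr_intervals <- function(rr) {
  if (inherits(rr, "rr_series") || is.data.frame(rr)) rr$interval_ms
  else as.numeric(rr)
}

#' Frequency-domain HRV indices
#'
#' See [spectral_config()] for the estimator. LF power, HF power and their
#' ratio; the ratio is `NA` with a warning when the HF band holds no power.
#'
#' @param rr an `rr_series` or numeric vector of RR intervals (ms), at least
#'   16 intervals.
#' @param cfg a [spectral_config()].
#' @return named list `lf_power`, `hf_power`, `lf_hf_ratio`.
#' @export
freq_domain <- function(rr, cfg = spectral_config()) {
  iv <- rr_intervals(rr)
  n <- length(iv)
  if (n < 16L) stop("need at least 16 intervals", call. = FALSE)
  if (cfg$fft_size < n) stop("`fft_size` smaller than the RR count", call. = FALSE)
  x <- iv - mean(iv)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
  s <- Mod(stats::fft(c(x * w, numeric(cfg$fft_size - n))))
  s <- if (cfg$mode == "power") s^2 else s
  f_eff <- 1000 / mean(iv)                      # beats/s
  fr <- (seq_len(cfg$fft_size) - 1L) * f_eff / cfg$fft_size
  lf <- sum(s[fr >= cfg$lf_band[1] & fr < cfg$lf_band[2]])
  hf <- sum(s[fr >= cfg$hf_band[1] & fr < cfg$hf_band[2]])
  ratio <- if (hf > 0) lf / hf else {
    warning("no HF power; LF/HF undefined"); NA_real_
  }
  list(lf_power = lf, hf_power = hf, lf_hf_ratio = ratio)
}

#' All HRV indices of one RR series
#'
#' @param rr an `rr_series` or numeric vector of RR intervals (ms).
#' @param cfg a [spectral_config()].
#' @return a one-row tibble: `mean_rr_ms`, `sdnn_ms`, `rmssd_ms`, `lf_power`,
#'   `hf_power`, `lf_hf_ratio`, `n_intervals`.
#' @export
hrv_indices <- function(rr, cfg = spectral_config()) {
  td <- time_domain(rr)
  fd <- freq_domain(rr, cfg)
  tibble::tibble(mean_rr_ms = td$mean_rr_ms, sdnn_ms = td$sdnn_ms,
                 rmssd_ms = td$rmssd_ms, lf_power = fd$lf_power,
                 hf_power = fd$hf_power, lf_hf_ratio = fd$lf_hf_ratio,
                 n_intervals = length(rr_intervals(rr)))
}

#' End-to-end HRV evaluation of one radar cube
#'
#' The full chain for a single 5-minute evaluation: phase compensation
#' against the reference bin, per-second movement scoring and CFAR flagging,
#' vital-bin selection and demodulation, amplitude-ordered peak detection,
#' movement-excluded RR construction, and HRV indices. Deterministic for a
#' fixed input cube.
#'
#' @param cube a raw [radar_cube()].
#' @param mask optional precomputed [detect_movement()] mask; computed from
#'   the compensated cube when `NULL`.
#' @param band an [hr_band()].
#' @param spec a [filter_spec()].
#' @param cfg a [spectral_config()].
#' @param method demodulation method, see [select_mp()].
#' @param R,limit peak-detector parameters; defaults from [default_R()].
#' @param alpha,trim CFAR parameters, see [detect_movement()].
#' @param trim_edges drop peaks inside the filter warm-up zones (half the
#'   band-pass kernel length at each record edge) before RR construction;
#'   edge transients otherwise fabricate peaks.
#' @param mask_pad_s seconds by which flagged movement seconds are padded on
#'   each side before RR exclusion, because motion artifact rings through the
#'   band-pass filter by its group delay; `NULL` (default) pads by the filter
#'   transient, 0 disables padding. The reported `movement_s` always counts
#'   the unpadded flags.
#' @return a one-row tibble as [hrv_indices()], plus `movement_s`, `n_peaks`
#'   and `mp_bin` columns; the intermediate objects are attached as
#'   attribute `stages` (list: `mask`, `mask_padded`, `vital`, `peaks`, `rr`).
#' @export
evaluate_hrv <- function(cube, mask = NULL, band = hr_band(),
                         spec = filter_spec(), cfg = spectral_config(),
                         method = c("phase", "real"), R = NULL, limit = NULL,
                         alpha = 5.0, trim = 0.1, trim_edges = TRUE,
                         mask_pad_s = NULL) {
  method <- match.arg(method)
  comp <- phase_compensate(cube)
  if (is.null(mask)) mask <- detect_movement(movement_statistic(comp),
                                             alpha = alpha, trim = trim)
  vital <- select_mp(comp, band = band, spec = spec, method = method)
  peaks <- detect_peaks(vital, R = R, limit = limit)
  if (trim_edges && peaks$n_candidates > 0L) {
    lo <- vital$transient
    hi <- length(vital$v0) - 1L - vital$transient
    keep <- peaks$indices >= lo & peaks$indices <= hi
    peaks$indices <- peaks$indices[keep]
    peaks$amplitudes <- peaks$amplitudes[keep]
    peaks$times_s <- peaks$times_s[keep]
  }
  if (is.null(mask_pad_s)) mask_pad_s <- ceiling(vital$transient / vital$fps)
  mask_padded <- pad_mask(mask, mask_pad_s)
  rr <- build_rr(peaks, mask = mask_padded)
  out <- hrv_indices(rr, cfg)
  out$movement_s <- attr(mask, "total_movement_s")
  out$n_peaks <- length(peaks$indices)
  out$mp_bin <- vital$mp_bin
  attr(out, "stages") <- list(mask = mask, mask_padded = mask_padded,
                              vital = vital, peaks = peaks, rr = rr)
  out
}
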