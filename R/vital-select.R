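#' Heart-rate frequency band
#'
#' The adult heart-rate band in the slow-time spectrum, 40/60 to 130/60 Hz
#' (40-130 beats per minute). The complement "noise band" used by
#' [band_ratio()] spans 0.05 Hz to the Nyquist frequency minus the HR band
#' (the 0.05 Hz floor excludes residual drift from the denominator).
#'
#' @param lo_hz,hi_hz band edges (Hz), `lo_hz < hi_hz`.
#' @param noise_floor_hz lower edge of the complement noise band.
#' @return a list of class `hr_band`.
#' @export
hr_band <- function(lo_hz = 40 / 60, hi_hz = 130 / 60, noise_floor_hz = 0.05) {
  if (lo_hz >= hi_hz) stop("`lo_hz` must be below `hi_hz`", call. = FALSE)
  structure(list(lo_hz = lo_hz, hi_hz = hi_hz,
                 noise_floor_hz = noise_floor_hz),
            class = "hr_band")
}

#' Heart-band to complement-band spectral power ratio
#'
#' Single-window periodogram ratio of a slow-time series: power summed over
#' the HR band `[lo, hi)` divided by power summed over the complement band
#' (`[noise_floor, fps/2]` minus the HR band). The periodogram is the squared
#' magnitude of the discrete Fourier transform of the mean-removed series.
#'
#' @param series numeric or complex slow-time series, at least 2 s of frames.
#' @param fps sampling rate (Hz).
#' @param band an [hr_band()].
#' @return a non-negative ratio; `Inf` with a warning when the complement
#'   band holds no power.
#' @export
band_ratio <- function(series, fps, band = hr_band()) {
  stopifnot(inherits(band, "hr_band"))
  n <- length(series)
  if (n < 2 * fps) stop("series shorter than 2 s", call. = FALSE)
  p <- Mod(stats::fft(series - mean(series)))^2
  fr <- (seq_len(n) - 1L) * fps / n
  in_hr <- fr >= band$lo_hz & fr < band$hi_hz
  in_noise <- fr >= band$noise_floor_hz & fr <= fps / 2 & !in_hr
  den <- sum(p[in_noise])
  if (den == 0) {
    warning("no power in the noise band; returning Inf")
    return(Inf)
  }
  sum(p[in_hr]) / den
}

#' Vital signal constructor (internal shape; see [select_mp()])
#' @noRd
new_vital_signal <- function(v0, fps, mp_bin, t0, transient = 0L) {
  structure(list(v0 = as.numeric(v0), fps = fps, mp_bin = as.integer(mp_bin),
                 t0 = t0, transient = as.integer(transient)),
            class = "vital_signal")
}

#' @export
print.vital_signal <- function(x, ...) {
  cat(sprintf("<vital_signal> bin %d, %d frames @ %g FPS (%.1f s)\n",
              x$mp_bin, length(x$v0), x$fps, length(x$v0) / x$fps))
  invisible(x)
}

#' Select the vital fast-time bin and extract the vital signal
#'
#' Scores every eligible fast-time bin (bins beyond `guard_m` past the start
#' range) by the ratio of heart-band spectral power to a noise reference and
#' returns the slow-time signal of the winning bin (the measurement point,
#' MP). Ties break to the lowest bin index.
#'
#' Two demodulation methods are provided:
#' * `"phase"` (default): the vital signal is the unwrapped phase of the
#'   compensated MP series, band-pass filtered by `spec`. Phase is the linear
#'   readout of chest displacement (`4 pi d(t) / lambda`), so heartbeat
#'   pulses keep a fixed sign regardless of the operating point.
#' * `"real"`: the vital signal is the real part of the band-passed MP
#'   series (pass an already band-passed cube, or let `spec` filter it).
#'
#' For ranking, the heart-band power of each bin's compensated (unfiltered)
#' spectrum is referenced to the bin's noise floor measured above
#' `noise_floor_ref_hz`, where no cardiorespiratory content exists; this is
#' monotone in target envelope power and therefore lands on the
#' best-illuminated bin. The complement-band ratio of [band_ratio()] remains
#' available for single-series diagnostics.
#'
#' @param cube a phase-compensated [radar_cube()].
#' @param band an [hr_band()].
#' @param spec a [filter_spec()] used to band-pass the vital series.
#' @param method `"phase"` or `"real"` demodulation.
#' @param guard_m eligible bins start `guard_m` metres past the start range.
#' @param noise_floor_ref_hz frequency above which the per-bin noise floor is
#'   measured for ranking.
#' @return a `vital_signal`: list with `v0` (the vital series), `fps`,
#'   `mp_bin` (0-based selected bin), `t0` and `transient` (filter warm-up
#'   length in frames at each record edge).
#' @export
select_mp <- function(cube, band = hr_band(), spec = filter_spec(),
                      method = c("phase", "real"), guard_m = 0.1,
                      noise_floor_ref_hz = 20) {
  stopifnot(inherits(cube, "radar_cube"))
  method <- match.arg(method)
  n <- ncol(cube$frames)
  first <- ceiling(guard_m / cube$bin_spacing) + 1L  # 1-based row index
  if (first > nrow(cube$frames)) stop("no eligible bins", call. = FALSE)
  elig <- first:nrow(cube$frames)

  x <- t(cube$frames[elig, , drop = FALSE])          # frames x bins
  x <- sweep(x, 2L, colMeans(x))
  p <- Mod(stats::mvfft(x))^2
  fr <- (seq_len(n) - 1L) * cube$fps / n
  in_hr <- fr >= band$lo_hz & fr < band$hi_hz
  in_floor <- fr >= noise_floor_ref_hz & fr <= cube$fps - noise_floor_ref_hz
  if (!any(in_floor))  # record too coarse for a separate floor estimate
    in_floor <- fr >= band$noise_floor_hz & fr <= cube$fps / 2 & !in_hr
  num <- colSums(p[in_hr, , drop = FALSE])
  den <- colSums(p[in_floor, , drop = FALSE])
  ratio <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  mp_j <- which.max(ratio)                           # which.max takes first tie
  mp_row <- elig[mp_j]

  kernel <- design_bandpass(spec, cube$fps)
  series <- cube$frames[mp_row, ]
  v0 <- switch(method,
    phase = apply_fir(unwrap_phase(Arg(series)), kernel),
    real  = apply_fir(Re(series), kernel))
  new_vital_signal(v0, fps = cube$fps, mp_bin = mp_row - 1L, t0 = cube$t0,
                   transient = attr(kernel, "delay"))
}

#' Unwrap a phase sequence
#'
#' Removes 2-pi jumps by wrapping successive differences into `(-pi, pi]`
#' and re-accumulating.
#'
#' @param p numeric phase sequence (radians).
#' @return unwrapped sequence, same length.
#' @export
unwrap_phase <- function(p) {
  if (length(p) < 2L) return(p)
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1L], dp))
}
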