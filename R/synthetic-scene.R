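#' Synthetic radar scene parameters
#'
#' Describes one simulated 5-minute evaluation of a seated subject. The chest
#' displacement is a respiration sinusoid plus one Gaussian pulse per
#' heartbeat, driven by a ground-truth RR series with low-frequency (LF) and
#' high-frequency (HF) sinusoidal modulation. The rendered cube adds a static
#' direct-path return at bin 0, a frame-common phase-jitter random walk,
#' complex white noise, and optional second-scale movement bursts.
#'
#' Displacement amplitudes are physiological textbook values: ~4 mm chest
#' excursion for quiet respiration, a few tenths of a millimetre for the
#' heartbeat (respiration dominates, which is the premise of heart-band bin
#' selection). The carrier wavelength 0.04 m corresponds to a 7.5 GHz centre
#' frequency.
#'
#' @param rr_mean_ms mean RR interval (ms).
#' @param rr_sd_ms total RR standard deviation (ms); the white component is
#'   sized so that LF + HF modulation plus noise gives approximately this SD.
#' @param lf_mod,hf_mod `c(amplitude_ms, frequency_hz)` of the LF and HF
#'   sinusoidal RR modulation.
#' @param resp_amp_m respiration displacement amplitude (m).
#' @param resp_freq_hz respiration frequency (Hz).
#' @param heart_amp_m heartbeat pulse displacement amplitude (m); must be
#'   smaller than `resp_amp_m`.
#' @param heart_pulse_width_s Gaussian pulse width (sigma, s).
#' @param target_range_m subject range (m); must lie inside the acquisition
#'   range window.
#' @param carrier_wavelength_m carrier wavelength (m).
#' @param envelope_sigma_m fast-time pulse envelope width (m), about the
#'   radar's ~1.5 cm range resolution.
#' @param direct_path_amp amplitude of the static bin-0 direct-path return,
#'   relative to the unit target envelope peak.
#' @param snr_db ratio of target envelope peak power to complex white noise
#'   power (dB); `Inf` disables noise.
#' @param phase_jitter_sd_rad per-frame step SD of the frame-common phase
#'   random walk; 0 disables jitter.
#' @param movement_bursts list of `c(start_s, duration_s, amplitude_m)`
#'   movement bursts (mean-reverting random-walk displacement with per-frame
#'   innovation SD `amplitude_m`).
#' @param seed integer seed making the scene a pure function of its parameters.
#' @return a list of class `scene_params`.
#' @export
scene_params <- function(rr_mean_ms = 800, rr_sd_ms = 40,
                         lf_mod = c(30, 0.10), hf_mod = c(20, 0.30),
                         resp_amp_m = 4e-3, resp_freq_hz = 0.25,
                         heart_amp_m = 3e-4, heart_pulse_width_s = 0.05,
                         target_range_m = 0.7, carrier_wavelength_m = 0.04,
                         envelope_sigma_m = 0.015, direct_path_amp = 5,
                         snr_db = 30, phase_jitter_sd_rad = 0.01,
                         movement_bursts = list(), seed = 1L) {
  if (rr_mean_ms <= 0) stop("`rr_mean_ms` must be positive", call. = FALSE)
  if (heart_amp_m >= resp_amp_m)
    stop("`heart_amp_m` must be smaller than `resp_amp_m`", call. = FALSE)
  structure(
    list(rr_mean_ms = rr_mean_ms, rr_sd_ms = rr_sd_ms,
         lf_mod = lf_mod, hf_mod = hf_mod,
         resp_amp_m = resp_amp_m, resp_freq_hz = resp_freq_hz,
         heart_amp_m = heart_amp_m, heart_pulse_width_s = heart_pulse_width_s,
         target_range_m = target_range_m,
         carrier_wavelength_m = carrier_wavelength_m,
         envelope_sigma_m = envelope_sigma_m,
         direct_path_amp = direct_path_amp, snr_db = snr_db,
         phase_jitter_sd_rad = phase_jitter_sd_rad,
         movement_bursts = movement_bursts, seed = as.integer(seed)),
    class = "scene_params")
}

#' Ground-truth RR series and beat times
#'
#' Builds a beat sequence whose i-th RR interval is
#' `rr_mean + A_lf sin(2 pi f_lf t_i) + A_hf sin(2 pi f_hf t_i) + eps_i`,
#' with `eps_i` white Gaussian noise sized so that the total RR SD is
#' approximately `rr_sd_ms` (the two sinusoids each contribute
#' `amplitude / sqrt(2)`). Beat times are the cumulative sums, starting at 0.
#'
#' @param params a [scene_params()].
#' @param duration_s record length (s); must exceed two mean RR intervals.
#' @return a list of class `ground_truth` with `beat_times_s` (strictly
#'   increasing), `rr_true_ms` (successive differences, ms), and
#'   `movement_seconds` (integer vector of flagged whole seconds, filled in by
#'   [render_cube()] from the burst list).
#' @export
generate_rr_series <- function(params, duration_s) {
  stopifnot(inherits(params, "scene_params"))
  if (duration_s <= 2 * params$rr_mean_ms / 1000)
    stop("`duration_s` too short for the requested mean RR", call. = FALSE)
  sin_var <- params$lf_mod[1]^2 / 2 + params$hf_mod[1]^2 / 2
  eps_sd <- sqrt(max(0, params$rr_sd_ms^2 - sin_var))
  withr_seed(params$seed, {
    bt <- 0
    beats <- numeric(0)
    repeat {
      beats <- c(beats, bt)
      rr <- params$rr_mean_ms +
        params$lf_mod[1] * sin(2 * pi * params$lf_mod[2] * bt) +
        params$hf_mod[1] * sin(2 * pi * params$hf_mod[2] * bt) +
        stats::rnorm(1, 0, eps_sd)
      if (rr <= 0) stop("parameters produced a non-positive RR interval", call. = FALSE)
      bt <- bt + rr / 1000
      if (bt >= duration_s) {  # keep the beat closing the final interval
        beats <- c(beats, bt)
        break
      }
    }
    structure(list(beat_times_s = beats,
                   rr_true_ms = diff(beats) * 1000,
                   movement_seconds = integer(0)),
              class = "ground_truth")
  })
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# chest displacement time series (m) for a truth + params on a frame grid
chest_displacement <- function(truth, params, n, fps) {
  tt <- (seq_len(n) - 1L) / fps
  d <- params$resp_amp_m * sin(2 * pi * params$resp_freq_hz * tt)
  hw <- params$heart_pulse_width_s
  for (b in truth$beat_times_s) {
    i0 <- max(1L, floor((b - 4 * hw) * fps) + 1L)
    i1 <- min(n, ceiling((b + 4 * hw) * fps) + 1L)
    if (i0 > i1) next
    idx <- i0:i1
    d[idx] <- d[idx] + params$heart_amp_m * exp(-((tt[idx] - b)^2) / (2 * hw^2))
  }
  d
}

# mean-reverting random-walk displacement for one movement burst
burst_displacement <- function(n_frames, step_sd, fps, tau_s = 0.5) {
  rho <- exp(-1 / (fps * tau_s))
  w <- stats::rnorm(n_frames, 0, step_sd)
  stats::filter(w, rho, method = "recursive")
}

#' Render a synthetic radar cube
#'
#' Maps the chest displacement `d(t)` onto a complex fast-time by slow-time
#' matrix: the target return at bin `k` is
#' `env(r_k - target_range - d(t)) * exp(1i * 4 * pi * (target_range + d(t)) / lambda)`
#' with a Gaussian range envelope; bin 0 carries a strong static direct-path
#' return; every frame is multiplied by a common jitter `exp(1i * theta_t)`
#' where `theta_t` is a random walk; complex white noise is added at `snr_db`.
#' Movement bursts add mean-reverting random-walk displacement and their
#' whole seconds are recorded in the returned truth.
#'
#' @param truth a [generate_rr_series()] result spanning `cfg$window_s`.
#' @param params a [scene_params()].
#' @param cfg an [acquisition_config()].
#' @return a list with `cube` (a [radar_cube()]) and `truth` (the input truth
#'   with `movement_seconds` filled in).
#' @export
render_cube <- function(truth, params, cfg = acquisition_config()) {
  stopifnot(inherits(truth, "ground_truth"), inherits(params, "scene_params"),
            inherits(cfg, "acquisition_config"))
  fps <- cfg$fps
  n <- round(cfg$window_s * fps)
  if (max(truth$beat_times_s) >= cfg$window_s + 1)
    warning("truth extends past the acquisition window; extra beats ignored")
  rk <- cfg$range_start_m +
    (seq_len(floor((cfg$range_max_m - cfg$range_start_m) / cfg$bin_spacing_m) + 1L) - 1L) *
    cfg$bin_spacing_m
  k_n <- length(rk)
  if (params$target_range_m <= cfg$range_start_m ||
      params$target_range_m >= cfg$range_max_m)
    stop("target range outside the acquisition range window", call. = FALSE)
  withr_seed(params$seed + 1L, {
    d <- chest_displacement(truth, params, n, fps)
    movement_seconds <- integer(0)
    tt <- (seq_len(n) - 1L) / fps
    for (bb in params$movement_bursts) {
      idx <- which(tt >= bb[1] & tt < bb[1] + bb[2])
      if (!length(idx)) next
      d[idx] <- d[idx] + burst_displacement(length(idx), bb[3], fps)
      movement_seconds <- union(movement_seconds,
                                seq.int(floor(bb[1]), ceiling(bb[1] + bb[2]) - 1L))
    }
    rt <- params$target_range_m + d
    lambda <- params$carrier_wavelength_m
    x <- matrix(0 + 0i, nrow = k_n, ncol = n)
    phase <- exp(4i * pi * rt / lambda)
    s_env <- params$envelope_sigma_m
    reach <- 8 * s_env + diff(range(d))
    for (k in which(abs(rk - params$target_range_m) <= reach)) {
      x[k, ] <- exp(-((rk[k] - rt)^2) / (2 * s_env^2)) * phase
    }
    x[1L, ] <- x[1L, ] + params$direct_path_amp
    if (params$phase_jitter_sd_rad > 0) {
      theta <- cumsum(stats::rnorm(n, 0, params$phase_jitter_sd_rad))
      x <- sweep(x, 2L, exp(1i * theta), `*`)
    }
    if (is.finite(params$snr_db)) {
      nsd <- sqrt(10^(-params$snr_db / 10) / 2)
      x <- x + matrix(complex(real = stats::rnorm(k_n * n, 0, nsd),
                              imaginary = stats::rnorm(k_n * n, 0, nsd)),
                      nrow = k_n)
    }
    truth$movement_seconds <- sort(movement_seconds)
    list(cube = radar_cube(x, fps = fps, range_start = cfg$range_start_m,
                           bin_spacing = cfg$bin_spacing_m, t0 = 0),
         truth = truth)
  })
}

#' Study-table generator parameters
#'
#' Distributions of the four HRV indices for the four VAS groups of a
#' simulated study. Group means default to the measured group averages of a
#' seated office-worker cohort (mean RR / SDNN / RMSSD / LF-HF per group);
#' between-evaluation SDs and radar-vs-reference measurement noise are
#' realistic choices documented in the methods vignette.
#'
#' @param group_n evaluations per group (control 1-3, then high distress).
#' @param group_means 4x4 matrix (rows = groups control1, control2, control3,
#'   high) of mean RR (ms), SDNN (ms), RMSSD (ms), LF/HF means.
#' @param index_sd between-evaluation SD of each index within a group.
#' @param method_noise_sd SD of the additive radar-minus-reference
#'   measurement noise per index; 0 makes radar and reference identical.
#' @param movement_mean_s mean per-evaluation movement duration (s), drawn
#'   from an exponential distribution.
#' @param seed integer seed.
#' @return a list of class `study_params`.
#' @export
study_params <- function(group_n = c(21, 20, 49, 12),
                         group_means = default_group_means(),
                         index_sd = c(mean_rr = 90, sdnn = 15,
                                      rmssd = 20, lf_hf = 0.25),
                         method_noise_sd = c(mean_rr = 2.6, sdnn = 6,
                                             rmssd = 20, lf_hf = 0.24),
                         movement_mean_s = 7.24, seed = 1L) {
  if (any(group_n < 1)) stop("group counts must be >= 1", call. = FALSE)
  if (any(index_sd < 0) || any(method_noise_sd < 0))
    stop("SDs must be non-negative", call. = FALSE)
  structure(list(group_n = group_n, group_means = group_means,
                 index_sd = index_sd, method_noise_sd = method_noise_sd,
                 movement_mean_s = movement_mean_s, seed = as.integer(seed)),
            class = "study_params")
}

#' @rdname study_params
#' @export
default_group_means <- function() {
  m <- rbind(control1 = c(840.61, 37.71, 50.35, 0.58),
             control2 = c(831.81, 37.86, 62.27, 0.56),
             control3 = c(822.08, 36.50, 49.86, 0.59),
             high     = c(727.87, 26.61, 42.50, 0.76))
  colnames(m) <- c("mean_rr", "sdnn", "rmssd", "lf_hf")
  m
}

# VAS values available in each group bin at 0.5 resolution
vas_pool <- function(group) {
  switch(group,
         control1 = seq(0, 2.0, by = 0.5),
         control2 = seq(2.5, 4.5, by = 0.5),
         control3 = seq(5.0, 7.0, by = 0.5),
         high     = seq(7.5, 10.0, by = 0.5))
}

#' Generate a synthetic evaluation table
#'
#' Draws one paired (radar, reference) set of HRV indices per evaluation from
#' the group distribution, plus a VAS score inside the group's bin
#' (half-open bins at 0 / 2.5 / 5.0 / 7.5, last bin closed at 10, resolution
#' 0.5). The reference value is the group draw; the radar value adds Gaussian
#' between-method noise, giving a tunable radar-vs-reference correlation.
#' SDNN and RMSSD draws are floored at 1 ms to keep them positive.
#'
#' @param params a [study_params()].
#' @return a tibble with one row per evaluation: `id`, `group`, `vas`,
#'   `movement_s`, `radar_*` and `ref_*` columns for the four indices.
#' @export
generate_study <- function(params = study_params()) {
  stopifnot(inherits(params, "study_params"))
  groups <- rownames(params$group_means)
  idx <- colnames(params$group_means)
  withr_seed(params$seed, {
    rows <- purrr::map2(groups, params$group_n, function(g, ng) {
      ref <- purrr::map(idx, function(j)
        stats::rnorm(ng, params$group_means[g, j], params$index_sd[[j]]))
      names(ref) <- idx
      rad <- purrr::map(idx, function(j)
        ref[[j]] + stats::rnorm(ng, 0, params$method_noise_sd[[j]]))
      names(rad) <- idx
      for (j in c("sdnn", "rmssd")) {
        ref[[j]] <- pmax(ref[[j]], 1)
        rad[[j]] <- pmax(rad[[j]], 1)
      }
      tibble::tibble(
        group = g,
        vas = sample(vas_pool(g), ng, replace = TRUE),
        movement_s = round(stats::rexp(ng, 1 / params$movement_mean_s), 1),
        radar_mean_rr = rad$mean_rr, radar_sdnn = rad$sdnn,
        radar_rmssd = rad$rmssd, radar_lf_hf = rad$lf_hf,
        ref_mean_rr = ref$mean_rr, ref_sdnn = ref$sdnn,
        ref_rmssd = ref$rmssd, ref_lf_hf = ref$lf_hf)
    })
    out <- dplyr::bind_rows(rows)
    dplyr::mutate(out, id = dplyr::row_number(), .before = 1L)
  })
}
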