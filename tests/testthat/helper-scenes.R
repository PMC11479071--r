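# Shared scene helpers. Small scenes (short window, reduced range span) keep
# unit tests fast; acceptance tests build full-size scenes themselves.

small_acq <- function(duration_s = 40) {
  acquisition_config(window_s = duration_s, range_max_m = 1.0)
}

make_scene <- function(seed = 1L, duration_s = 40, snr_db = 60,
                       movement_bursts = list(), phase_jitter_sd_rad = 0.01,
                       ...) {
  sp <- scene_params(snr_db = snr_db, movement_bursts = movement_bursts,
                     phase_jitter_sd_rad = phase_jitter_sd_rad,
                     seed = seed, ...)
  truth <- generate_rr_series(sp, duration_s)
  scene <- render_cube(truth, sp, small_acq(duration_s))
  scene$params <- sp
  scene
}

withr_tempfile <- function(name) tempfile(fileext = paste0("-", name))

# one cached clean scene reused by several unit test files
cached_scene <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- make_scene(seed = 101L)
    val
  }
})
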