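test_that("scene_params validates physiological constraints", {
  expect_s3_class(scene_params(), "scene_params")
  expect_error(scene_params(rr_mean_ms = -1), "positive")
  expect_error(scene_params(heart_amp_m = 5e-3, resp_amp_m = 4e-3), "smaller")
})

test_that("ground-truth RR series satisfies its invariants", {
  sp <- scene_params(seed = 3)
  tr <- generate_rr_series(sp, 120)
  expect_equal(tr$rr_true_ms, diff(tr$beat_times_s) * 1000)
  expect_true(all(diff(tr$beat_times_s) > 0))
  expect_true(all(tr$rr_true_ms > 300 & tr$rr_true_ms < 2000))
  expect_equal(tr$beat_times_s[1], 0)
  expect_gte(max(tr$beat_times_s), 120)
  # requested moments are approximately recovered
  expect_lt(abs(mean(tr$rr_true_ms) - sp$rr_mean_ms), 15)
  expect_lt(abs(sd(tr$rr_true_ms) - sp$rr_sd_ms), 12)
  expect_error(generate_rr_series(sp, 1), "too short")
})

test_that("scenes are pure functions of parameters and seed", {
  a <- make_scene(seed = 11, duration_s = 20)
  b <- make_scene(seed = 11, duration_s = 20)
  c <- make_scene(seed = 12, duration_s = 20)
  expect_identical(a$cube$frames, b$cube$frames)
  expect_identical(a$truth$beat_times_s, b$truth$beat_times_s)
  expect_false(identical(a$cube$frames, c$cube$frames))
})

test_that("scene generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_rr_series(scene_params(seed = 4), 30))
  expect_identical(.Random.seed, before)
})

test_that("rendered cube has the advertised structure", {
  sc <- make_scene(seed = 21, duration_s = 20, snr_db = Inf,
                   phase_jitter_sd_rad = 0)
  cu <- sc$cube
  acq <- small_acq(20)
  expect_equal(ncol(cu$frames), 20 * 250)
  expect_equal(nrow(cu$frames),
               floor((acq$range_max_m - acq$range_start_m) /
                     acq$bin_spacing_m) + 1L)
  # bin 0 is the static direct path
  expect_equal(cu$frames[1, ], rep(5 + 0i, ncol(cu$frames)),
               tolerance = 1e-12)
  # strongest vital bin sits at the target range
  mean_amp <- rowMeans(Mod(cu$frames))
  mean_amp[1] <- 0
  k <- which.max(mean_amp) - 1L
  expect_lt(abs(bin_ranges(cu)[k + 1L] - sc$params$target_range_m), 0.02)
  # phase of the target bin tracks 4*pi*(r + d)/lambda
  ph <- unwrap_phase(Arg(cu$frames[k + 1L, ]))
  expect_gt(diff(range(ph)), 2)  # ~4 mm excursion on a 4 cm carrier
})

test_that("snr controls the added noise", {
  clean <- make_scene(seed = 31, duration_s = 20, snr_db = Inf,
                      phase_jitter_sd_rad = 0)
  noisy <- make_scene(seed = 31, duration_s = 20, snr_db = 20,
                      phase_jitter_sd_rad = 0)
  resid <- noisy$cube$frames - clean$cube$frames
  # complex noise power should be about 10^(-20/10) = 0.01
  expect_lt(abs(mean(Mod(resid)^2) - 0.01) / 0.01, 0.05)
})

test_that("movement bursts are recorded as whole seconds", {
  sc <- make_scene(seed = 41, duration_s = 20,
                   movement_bursts = list(c(8, 2.5, 5e-3)))
  expect_equal(sc$truth$movement_seconds, 8:10)
})

test_that("out-of-window target range is rejected", {
  sp <- scene_params(target_range_m = 2.0)
  tr <- generate_rr_series(sp, 10)
  expect_error(render_cube(tr, sp, small_acq(10)), "range window")
})

test_that("study generator produces the advertised table", {
  st <- generate_study(study_params(seed = 6))
  expect_equal(nrow(st), sum(c(21, 20, 49, 12)))
  expect_true(all(c("id", "group", "vas", "movement_s",
                    "radar_mean_rr", "radar_sdnn", "radar_rmssd",
                    "radar_lf_hf", "ref_mean_rr", "ref_sdnn", "ref_rmssd",
                    "ref_lf_hf") %in% names(st)))
  # VAS scores live in the group's bin at 0.5 resolution
  expect_true(all(st$vas[st$group == "control1"] <= 2.0))
  expect_true(all(st$vas[st$group == "high"] >= 7.5))
  expect_true(all(st$vas * 2 == round(st$vas * 2)))
  expect_true(all(st$radar_sdnn >= 1 & st$radar_rmssd >= 1))
  # reproducible, and zero method noise makes radar == reference
  st2 <- generate_study(study_params(seed = 6))
  expect_identical(st, st2)
  st0 <- generate_study(study_params(
    method_noise_sd = c(mean_rr = 0, sdnn = 0, rmssd = 0, lf_hf = 0),
    seed = 6))
  expect_equal(st0$radar_mean_rr, st0$ref_mean_rr)
})
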