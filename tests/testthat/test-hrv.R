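test_that("build_rr converts beat times to ms intervals", {
  rr <- build_rr(c(0, 0.8, 1.65, 2.4))
  expect_s3_class(rr, "rr_series")
  expect_equal(rr$interval_ms, c(800, 850, 750))
  expect_equal(rr$start_s, c(0, 0.8, 1.65))
  expect_equal(rr$end_s, c(0.8, 1.65, 2.4))
  expect_equal(attr(rr, "n_excluded_movement"), 0)
  # frame indices with fps
  rr2 <- build_rr(c(0, 200, 400), fps = 250)
  expect_equal(rr2$interval_ms, c(800, 800))
  expect_error(build_rr(1.0), "at least 2")
  expect_error(build_rr(c(1, 1, 2)), "strictly increasing")
})

test_that("movement exclusion drops every interval intersecting a flagged second", {
  mask <- tibble::tibble(second = 0:9,
                         flagged = 0:9 %in% c(4, 7))
  beats <- c(0.5, 1.3, 2.1, 3.0, 3.9, 4.7, 5.5, 6.4, 7.2, 8.1, 8.9, 9.6)
  rr <- build_rr(beats, mask = mask)
  # flagged windows are [4,5) and [7,8)
  overlaps <- function(s, e) any((e > c(4, 7)) & (s < c(4, 7) + 1))
  kept <- !mapply(overlaps, beats[-length(beats)], beats[-1])
  expect_equal(rr$start_s, beats[-length(beats)][kept])
  expect_equal(attr(rr, "n_excluded_movement"), sum(!kept))
  # an interval fully containing a flagged second is also dropped
  rr3 <- build_rr(c(3.5, 5.5), mask = mask)
  expect_equal(nrow(rr3), 0)
  # boundaries: an interval ending exactly at the flagged start and one
  # starting exactly at the flagged end both survive; [4,5] is dropped
  rr4 <- build_rr(c(3.0, 4.0, 5.0, 6.0), mask = mask)
  expect_equal(rr4$interval_ms, c(1000, 1000))
  expect_equal(rr4$start_s, c(3, 5))
})

test_that("time-domain indices match hand computation", {
  iv <- c(800, 820, 790, 805, 830)
  td <- time_domain(iv)
  expect_equal(td$mean_rr_ms, mean(iv))
  expect_equal(td$sdnn_ms, sqrt(sum((iv - mean(iv))^2) / 4))
  expect_equal(td$rmssd_ms, sqrt(mean(c(20, -30, 15, 25)^2)))
  tdp <- time_domain(iv, population = TRUE)
  expect_equal(tdp$sdnn_ms, sqrt(mean((iv - mean(iv))^2)))
  expect_true(is.na(time_domain(c(800, 810))$rmssd_ms))
  expect_error(time_domain(800), "2 intervals")
})

test_that("frequency-domain estimator localises RR modulation", {
  n <- 256
  base <- 800
  lf <- base + 40 * sin(2 * pi * 0.10 * (0:(n - 1)) * base / 1000)
  hf <- base + 40 * sin(2 * pi * 0.30 * (0:(n - 1)) * base / 1000)
  f_lf <- freq_domain(lf)
  f_hf <- freq_domain(hf)
  expect_gt(f_lf$lf_hf_ratio, 5)
  expect_lt(f_hf$lf_hf_ratio, 0.2)
  expect_gt(f_lf$lf_power, f_lf$hf_power)
  expect_error(freq_domain(rep(800, 10)), "16 intervals")
  expect_error(freq_domain(rep(800, 20), spectral_config(fft_size = 16)),
               "smaller")
  # a constant RR series has no spectral power at all
  expect_warning(f0 <- freq_domain(rep(800, 20)), "no HF power")
  expect_true(is.na(f0$lf_hf_ratio))
})

test_that("band edges are half-open: 0.15 Hz belongs to HF", {
  cfg <- spectral_config()
  fr <- c(0.0499, 0.05, 0.1499, 0.15, 0.3999, 0.40)
  in_lf <- fr >= cfg$lf_band[1] & fr < cfg$lf_band[2]
  in_hf <- fr >= cfg$hf_band[1] & fr < cfg$hf_band[2]
  expect_equal(in_lf, c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(in_hf, c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_false(any(in_lf & in_hf))
  expect_error(spectral_config(fft_size = 1000), "power of two")
  expect_error(spectral_config(lf_band = c(0.05, 0.2)), "disjoint")
})

test_that("hrv_indices returns a one-row tibble of all indices", {
  set.seed(11)
  iv <- rnorm(100, 800, 30)
  out <- hrv_indices(iv)
  expect_equal(nrow(out), 1)
  expect_named(out, c("mean_rr_ms", "sdnn_ms", "rmssd_ms", "lf_power",
                      "hf_power", "lf_hf_ratio", "n_intervals"))
  expect_equal(out$n_intervals, 100)
  expect_equal(out$mean_rr_ms, mean(iv))
})

test_that("evaluate_hrv recovers the truth on a clean small scene", {
  sc <- cached_scene()
  res <- evaluate_hrv(sc$cube)
  st <- attr(res, "stages")
  true_iv <- sc$truth$rr_true_ms
  expect_lt(abs(res$mean_rr_ms - mean(true_iv)), 8)
  expect_lt(abs(res$sdnn_ms - sd(true_iv)) / sd(true_iv), 0.25)
  expect_equal(res$movement_s, 0)
  expect_equal(res$mp_bin, st$vital$mp_bin)
  expect_equal(res$n_peaks, length(st$peaks$indices))
  # edge-trimmed: no peak inside the filter warm-up zones
  expect_gte(min(st$peaks$indices), st$vital$transient)
  expect_lte(max(st$peaks$indices),
             length(st$vital$v0) - 1 - st$vital$transient)
})
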