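test_that("filter_spec validates the band", {
  expect_s3_class(filter_spec(), "filter_spec")
  expect_error(filter_spec(lowpass_cutoff_hz = 0.5), "highpass_cutoff_hz")
  expect_error(filter_spec(highpass_cutoff_hz = 0), "highpass_cutoff_hz")
})

test_that("band-pass cascade meets the response requirements", {
  k <- design_bandpass(filter_spec(), fps = 250)
  mag <- function(f) Mod(filter_response(k, f))
  # respiration at 0.25 Hz attenuated by at least 20 dB (cascade: ~90 dB)
  expect_lt(20 * log10(mag(0.25)), -20)
  # heartbeat at 1.2 Hz passed within 3 dB
  expect_gt(20 * log10(mag(1.2)), -3)
  # stop-band above the low-pass cutoff
  expect_lt(20 * log10(mag(20)), -20)
  # odd length, linear phase (symmetric taps), delay = (len-1)/2
  expect_equal(length(k) %% 2, 1)
  expect_equal(as.numeric(k), rev(as.numeric(k)), tolerance = 1e-12)
  expect_equal(attr(k, "delay"), (length(k) - 1) / 2)
})

test_that("single-edge high-pass variant is config-selectable", {
  k <- design_bandpass(filter_spec(highpass_cutoff_hz = 40 / 60), fps = 250)
  expect_equal(length(k), 31 + 1001 - 1)
  expect_lt(20 * log10(Mod(filter_response(k, 0.25))), -20)
  expect_error(design_bandpass(filter_spec(lowpass_cutoff_hz = 300,
                                           highpass_cutoff_hz = 200),
                               fps = 250), "Nyquist")
})

test_that("apply_fir matches direct convolution away from the edges", {
  set.seed(7)
  k <- design_bandpass(filter_spec(highpass_order = 100), fps = 50)
  x <- rnorm(1200)
  y <- apply_fir(x, k)
  ref <- stats::convolve(x, rev(as.numeric(k)), type = "open")
  d <- attr(k, "delay")
  core <- (length(k) + 1):(1200 - length(k))
  expect_equal(y[core], ref[core + d], tolerance = 1e-10)
  # matrix form filters columns identically
  ym <- apply_fir(cbind(x, 2 * x), k)
  expect_equal(ym[, 1], y, tolerance = 1e-12)
  expect_equal(ym[, 2], 2 * y, tolerance = 1e-12)
  # complex input stays complex
  expect_true(is.complex(apply_fir(x + 1i * x, k)))
  expect_error(apply_fir(rnorm(10), k), "shorter")
})

test_that("delay removal keeps a passband sine aligned", {
  k <- design_bandpass(filter_spec(), fps = 250)
  tt <- (0:9999) / 250
  x <- sin(2 * pi * 1.2 * tt)
  y <- apply_fir(x, k)
  core <- 3000:7000
  g <- Mod(filter_response(k, 1.2))
  expect_lt(max(abs(y[core] - g * x[core])), 0.02)
})

test_that("replicate padding avoids large-offset edge transients", {
  k <- design_bandpass(filter_spec(), fps = 250)
  x <- 220 + sin(2 * pi * 1.2 * (0:9999) / 250)  # unwrapped-phase-like offset
  y <- apply_fir(x, k)
  expect_lt(max(abs(y)), 2)  # no hundreds-sized edge spikes
})

test_that("phase compensation zeroes the reference and cancels jitter", {
  set.seed(8)
  n <- 500
  base <- matrix(complex(real = rnorm(3 * n), imaginary = rnorm(3 * n)), 3, n)
  base[1, ] <- 4 + 0i
  theta <- cumsum(rnorm(n, 0, 0.05))
  jit <- sweep(base, 2, exp(1i * theta), `*`)
  comp <- phase_compensate(radar_cube(jit, fps = 250))
  ref0 <- phase_compensate(radar_cube(base, fps = 250))
  expect_lt(max(abs(Arg(comp$frames[1, ]))), 1e-12)
  expect_equal(Mod(comp$frames), Mod(jit), tolerance = 1e-12)
  expect_lt(max(Mod(comp$frames - ref0$frames)), 1e-9)
})

test_that("phase compensation rejects a dead reference sample", {
  m <- matrix(1 + 1i, 2, 4)
  m[1, 3] <- 0 + 0i
  expect_error(phase_compensate(radar_cube(m, fps = 4)), "frame\\(s\\) 2")
  expect_error(phase_compensate(radar_cube(matrix(1 + 1i, 2, 4), fps = 4),
                                ref_bin = 5), "out of range")
})

test_that("bandpass_slowtime filters every bin and keeps dimensions", {
  set.seed(9)
  n <- 6000
  tt <- (0:(n - 1)) / 250
  sig <- sin(2 * pi * 1.2 * tt)
  drift <- sin(2 * pi * 0.25 * tt)
  m <- rbind(sig + drift, 2 * (sig + drift)) + 0i
  out <- bandpass_slowtime(radar_cube(m, fps = 250))
  expect_equal(dim(out$frames), dim(m))
  core <- 2500:3500
  g <- Mod(filter_response(design_bandpass(filter_spec(), 250), 1.2))
  expect_lt(max(abs(Re(out$frames[1, core]) - g * sig[core])), 0.05)
  expect_error(bandpass_slowtime(radar_cube(m[, 1:100], fps = 250)),
               "shorter")
})
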