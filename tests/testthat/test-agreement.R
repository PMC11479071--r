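fake_records <- function(n = 20, seed = 1, noise = 0) {
  set.seed(seed)
  ref <- tibble::tibble(
    ref_mean_rr = rnorm(n, 800, 60), ref_sdnn = rnorm(n, 40, 10),
    ref_rmssd = rnorm(n, 50, 12), ref_lf_hf = rnorm(n, 0.6, 0.1))
  dplyr::mutate(ref,
    radar_mean_rr = ref_mean_rr + rnorm(n, 0, noise),
    radar_sdnn = ref_sdnn + rnorm(n, 0, noise),
    radar_rmssd = ref_rmssd + rnorm(n, 0, noise),
    radar_lf_hf = ref_lf_hf + rnorm(n, 0, noise / 100))
}

test_that("outlier rules flag RMSSD cap and SDNN range violations", {
  rec <- fake_records(10)
  rec$radar_rmssd[2] <- 150                    # cap violation
  rec$radar_sdnn[5] <- max(rec$ref_sdnn) + 5   # above reference range
  rec$radar_sdnn[7] <- min(rec$ref_sdnn) - 5   # below reference range
  rec$radar_rmssd[7] <- 120                    # double violation
  out <- apply_outlier_rules(rec)
  expect_equal(which(!out$valid), c(2, 5, 7))
  expect_equal(out$reason[c(2, 5, 7)], c("rmssd", "sdnn", "rmssd,sdnn"))
  expect_true(all(out$reason[out$valid] == ""))
  expect_equal(nrow(filter_valid(out)), 7)
  # idempotent: re-applying to the flagged table changes nothing
  again <- apply_outlier_rules(out)
  expect_equal(again$valid, out$valid)
  # fixed bounds override the data-derived range
  fb <- apply_outlier_rules(rec, sdnn_bounds = c(-Inf, Inf))
  expect_equal(which(!fb$valid), c(2, 7))
})

test_that("pearson matches cor.test and validates input", {
  set.seed(2)
  x <- rnorm(30); y <- x + rnorm(30)
  p <- pearson(x, y)
  ct <- cor.test(x, y)
  expect_equal(p$r, unname(ct$estimate))
  expect_equal(p$p, ct$p.value)
  expect_equal(p$n, 30)
  expect_error(pearson(x, y[1:10]), "length")
  expect_error(pearson(1:2, 2:3), "n >= 3")
  expect_error(pearson(rep(1, 5), rnorm(5)), "variance")
})

test_that("bland_altman computes bias and 1.96-SD limits", {
  x <- c(10, 12, 11, 13, 14)
  y <- c(11, 13, 13, 14, 14)
  ba <- bland_altman(x, y)
  d <- y - x
  expect_equal(ba$bias, mean(d))
  expect_equal(ba$loa_low, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_high, mean(d) + 1.96 * sd(d))
  expect_equal(ba$n, 5)
  expect_error(bland_altman(1, 2), "n >= 2")
})

test_that("icc_2_1 matches the frozen external oracle", {
  # Oracle: pingouin 0.5.x intraclass_corr ICC(A,1) on this exact table
  # (x = rnorm(40, 50, 12), y = x + rnorm(40, 2, 6), seed 42, rounded to 6 dp)
  set.seed(42)
  x <- round(rnorm(40, 50, 12), 6)
  y <- round(x + rnorm(40, 2, 6), 6)
  ic <- icc_2_1(x, y)
  expect_equal(ic$icc, 0.9231308522, tolerance = 1e-9)
  expect_equal(round(ic$ci_low, 2), 0.84)
  expect_equal(round(ic$ci_high, 2), 0.96)
  expect_error(icc_2_1(1:3, 1:3), "n >= 5")
})

test_that("agreement identities hold", {
  rec <- fake_records(25, seed = 3, noise = 0)
  rep0 <- agreement_report(rec)
  tb <- tidy(rep0)
  expect_equal(tb$pearson_r, rep(1, 4), tolerance = 1e-12)
  expect_equal(tb$bias, rep(0, 4), tolerance = 1e-12)
  expect_equal(tb$loa_low, rep(0, 4), tolerance = 1e-12)
  expect_equal(tb$loa_high, rep(0, 4), tolerance = 1e-12)
  expect_equal(tb$icc, rep(1, 4), tolerance = 1e-12)
  # a pure mean shift keeps r = 1 but destroys absolute agreement
  x <- rec$ref_sdnn
  shifted <- icc_2_1(x, x + 30)
  expect_equal(pearson(x, x + 30)$r, 1)
  expect_lt(shifted$icc, 0.3)
})

test_that("agreement_report drops flagged rows and glance summarises", {
  rec <- fake_records(20, seed = 4, noise = 2)
  rec$valid <- TRUE
  rec$valid[3] <- FALSE
  rep1 <- agreement_report(rec)
  expect_equal(nrow(rep1$records), 19)
  g <- glance(rep1)
  expect_equal(g$n, 19)
  expect_equal(g$n_indices, 4)
  expect_output(print(rep1), "agreement_report")
})
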