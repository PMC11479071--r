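test_that("VAS bins are half-open with a closed top bin", {
  g <- assign_groups(c(0, 2.4, 2.5, 4.9, 5, 7.4, 7.5, 9.9, 10))
  expect_equal(as.character(g),
               c("low", "low", "mild", "mild", "moderate", "moderate",
                 "high", "high", "high"))
  expect_equal(levels(g), c("low", "mild", "moderate", "high"))
  expect_error(assign_groups(c(1, 11)), "outside")
  expect_error(group_spec(edges = c(0, 5, 5, 10)), "strictly increasing")
  expect_error(group_spec(labels = c("a", "b")), "one label")
})

test_that("two-group ANOVA equals the squared pooled t test", {
  set.seed(5)
  v <- c(rnorm(20, 10), rnorm(15, 12))
  g <- rep(c("a", "b"), c(20, 15))
  an <- anova_two_group(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(an$f, unname(tt$statistic)^2)
  expect_equal(an$p, tt$p.value)
  expect_equal(an$df1, 1)
  expect_equal(an$df2, 33)
  expect_equal(unname(an$means), c(mean(v[1:20]), mean(v[21:35])))
  expect_error(anova_two_group(v, rep("a", 35)), "two")
  expect_error(anova_two_group(v[1:3], c("a", "a", "b")), "n >= 2")
})

test_that("index orientation is fixed a priori", {
  expect_equal(index_orientation("mean_rr"), "low")
  expect_equal(index_orientation("sdnn"), "low")
  expect_equal(index_orientation("rmssd"), "low")
  expect_equal(index_orientation("lf_hf"), "high")
  expect_error(index_orientation("foo"))
})

test_that("AUC equals the Mann-Whitney U normalisation", {
  set.seed(6)
  v <- rnorm(60)
  pos <- rep(c(TRUE, FALSE), 30)
  rc <- roc_analysis(v, pos, orientation = "high")
  # U normalisation: P(value_pos > value_neg) + 0.5 P(equal)
  u <- mean(outer(v[pos], v[!pos], function(a, b)
    (a > b) + 0.5 * (a == b)))
  expect_equal(rc$auc, u, tolerance = 1e-12)
  rc_low <- roc_analysis(v, pos, orientation = "low")
  u_low <- mean(outer(v[pos], v[!pos], function(a, b)
    (a < b) + 0.5 * (a == b)))
  expect_equal(rc_low$auc, u_low, tolerance = 1e-12)
})

test_that("perfect separation gives AUC 1 and a perfect threshold", {
  v <- c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1))
  pos <- rep(c(FALSE, TRUE), each = 20)
  rc <- roc_analysis(v, pos, orientation = "high")
  expect_equal(rc$auc, 1)
  expect_equal(rc$sensitivity, 1)
  expect_equal(rc$specificity, 1)
  expect_error(roc_analysis(v, rep(TRUE, 40)), "both classes")
})

test_that("orientation flip maps AUC to its complement", {
  set.seed(7)
  v <- c(rnorm(50, 0), rnorm(50, 1))
  pos <- rep(c(FALSE, TRUE), each = 50)
  a_hi <- roc_analysis(v, pos, orientation = "high")$auc
  a_lo <- roc_analysis(v, pos, orientation = "low")$auc
  expect_equal(a_hi + a_lo, 1, tolerance = 1e-12)
})

test_that("top-left threshold breaks ties toward higher sensitivity", {
  # two points at the same distance from (0, 1): the higher-sensitivity wins
  curve <- tibble::tibble(threshold = c(1, 2),
                          sensitivity = c(0.7, 0.9),
                          specificity = c(0.9, 0.7))
  best <- topleft_threshold(curve)
  expect_equal(best$threshold, 2)
  expect_equal(best$sensitivity, 0.9)
})

test_that("top-left threshold on symmetric Gaussians sits near the midpoint", {
  set.seed(8)
  v <- c(rnorm(3000, 0), rnorm(3000, 2))
  pos <- rep(c(FALSE, TRUE), each = 3000)
  rc <- roc_analysis(v, pos, orientation = "high")
  expect_lt(abs(rc$threshold - 1), 0.1)
})

test_that("distress_report compares extreme groups and classifies high", {
  st <- generate_study(study_params(seed = 10))
  rep1 <- distress_report(st)
  tb <- tidy(rep1)
  expect_equal(tb$index, c("mean_rr", "sdnn", "rmssd", "lf_hf"))
  expect_true(all(tb$auc >= 0 & tb$auc <= 1))
  expect_true(all(tb$p >= 0 & tb$p <= 1))
  # generator group means: high group lower mean RR than low-distress group
  expect_lt(tb$mean_high[tb$index == "mean_rr"],
            tb$mean_low[tb$index == "mean_rr"])
  g <- glance(rep1)
  expect_equal(g$n, nrow(st))
  expect_output(print(rep1), "distress_report")
  expect_s3_class(rep1$roc$mean_rr, "roc_result")
})
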