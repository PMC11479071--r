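#' Flag invalid evaluations (outlier rules)
#'
#' An evaluation is invalid when the radar RMSSD exceeds `rmssd_cap`, or when
#' the radar SDNN falls outside the range of the reference SDNN. By default
#' that range is the observed `[min, max]` of `ref_sdnn` over the input table
#' (the rule a validation study applies to its own data); fixed bounds can be
#' supplied instead, e.g. `c(8.3, 98.4)` ms.
#'
#' Flagging is idempotent: the bounds are computed from the full input table,
#' not from the survivors, so re-applying the rules does not change the
#' flags.
#'
#' @param records a tibble with `radar_rmssd`, `radar_sdnn`, `ref_sdnn`
#'   columns (as from [generate_study()]).
#' @param rmssd_cap radar RMSSD cap in ms.
#' @param sdnn_bounds optional fixed `c(lo, hi)` bounds for radar SDNN.
#' @return the input tibble with logical `valid` and character `reason`
#'   columns (`reason` is `""` for valid records, otherwise a comma-separated
#'   list of violated rules).
#' @export
apply_outlier_rules <- function(records, rmssd_cap = 100, sdnn_bounds = NULL) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  if (is.null(sdnn_bounds)) sdnn_bounds <- range(records$ref_sdnn)
  bad_rmssd <- records$radar_rmssd > rmssd_cap
  bad_sdnn <- records$radar_sdnn < sdnn_bounds[1] |
    records$radar_sdnn > sdnn_bounds[2]
  reason <- dplyr::case_when(
    bad_rmssd & bad_sdnn ~ "rmssd,sdnn",
    bad_rmssd ~ "rmssd",
    bad_sdnn ~ "sdnn",
    TRUE ~ "")
  dplyr::mutate(records, valid = !(bad_rmssd | bad_sdnn), reason = reason)
}

#' Keep only valid evaluations
#' @param records output of [apply_outlier_rules()].
#' @return the valid rows.
#' @export
filter_valid <- function(records) dplyr::filter(records, .data$valid)

#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation and the two-sided p-value from the t transform
#' with n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y paired numeric vectors, n >= 3, non-zero variances.
#' @return named list `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Bland-Altman bias and limits of agreement
#'
#' Differences `d = y - x`; bias is `mean(d)` and the limits of agreement are
#' `bias +/- 1.96 * sd(d)` (sample SD).
#'
#' @param x reference-method values; `y` test-method values, same length >= 2.
#' @param y see `x`.
#' @return named list `bias`, `loa_low`, `loa_high`, `sd_diff`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length", call. = FALSE)
  if (length(x) < 2L) stop("need n >= 2", call. = FALSE)
  d <- y - x
  s <- stats::sd(d)
  list(bias = mean(d), loa_low = mean(d) - 1.96 * s,
       loa_high = mean(d) + 1.96 * s, sd_diff = s, n = length(x))
}

#' ICC(2,1): two-way random effects, absolute agreement, single measure
#'
#' From the two-way ANOVA mean squares of an n-subjects x k-raters layout
#' (here k = 2 methods):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' with the F-based confidence interval of Shrout & Fleiss / McGraw & Wong.
#'
#' @param x,y paired measurements of the same n >= 5 subjects by two methods.
#' @param conf confidence level of the interval.
#' @return named list `icc`, `ci_low`, `ci_high`, `n`.
#' @export
icc_2_1 <- function(x, y, conf = 0.95) {
  if (length(x) != length(y)) stop("`x` and `y` differ in length", call. = FALSE)
  n <- length(x)
  if (n < 5L) stop("need n >= 5 pairs", call. = FALSE)
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) -
              outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0) stop("degenerate mean squares", call. = FALSE)
  icc <- (msr - mse) / denom

  alpha <- 1 - conf
  if (mse <= 0) {  # perfect agreement: interval collapses
    return(list(icc = icc, ci_low = icc, ci_high = icc, n = n))
  }
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci_low = lo, ci_high = hi, n = n)
}

#' Radar-vs-reference agreement report
#'
#' Pearson correlation, Bland-Altman bias and limits of agreement, and
#' ICC(2,1) with its confidence interval, for each HRV index of a (validity-
#' filtered) evaluation table.
#'
#' @param records a tibble with paired `radar_<index>` / `ref_<index>`
#'   columns; rows flagged invalid by [apply_outlier_rules()] are dropped if
#'   a `valid` column is present.
#' @param indices character vector of index names.
#' @return an object of class `agreement_report`; use [tidy()] for the
#'   per-index statistics tibble and [glance()] for a one-row summary.
#' @export
agreement_report <- function(records,
                             indices = c("mean_rr", "sdnn", "rmssd", "lf_hf")) {
  stopifnot(is.data.frame(records))
  if ("valid" %in% names(records)) records <- filter_valid(records)
  stats_tbl <- purrr::map_dfr(indices, function(j) {
    x <- records[[paste0("ref_", j)]]
    y <- records[[paste0("radar_", j)]]
    pr <- pearson(x, y)
    ba <- bland_altman(x, y)
    ic <- icc_2_1(x, y)
    tibble::tibble(index = j, n = pr$n, pearson_r = pr$r, p_value = pr$p,
                   bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
                   icc = ic$icc, icc_ci_low = ic$ci_low, icc_ci_high = ic$ci_high)
  })
  structure(list(stats = stats_tbl, records = records, indices = indices),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d evaluations, %d indices\n",
              nrow(x$records), length(x$indices)))
  print(x$stats)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname agreement_report
#' @param x an `agreement_report`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.agreement_report <- function(x, ...) x$stats

#' @rdname agreement_report
#' @exportS3Method generics::glance
glance.agreement_report <- function(x, ...) {
  tibble::tibble(n = nrow(x$records), n_indices = length(x$indices),
                 min_r = min(x$stats$pearson_r), min_icc = min(x$stats$icc))
}
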