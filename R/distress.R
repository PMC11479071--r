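#' Distress group specification
#'
#' Self-reported distress on a 0-10 visual-analogue scale (VAS) is binned
#' into four groups at edges 0, 2.5, 5, 7.5, 10. Bins are half-open
#' `[lo, hi)` except the last, which is closed at 10, so a score of exactly
#' 7.5 falls in the highest group.
#'
#' @param edges increasing numeric bin edges.
#' @param labels one label per bin.
#' @return a list of class `group_spec`.
#' @export
group_spec <- function(edges = c(0, 2.5, 5, 7.5, 10),
                       labels = c("low", "mild", "moderate", "high")) {
  if (is.unsorted(edges, strictly = TRUE))
    stop("`edges` must be strictly increasing", call. = FALSE)
  if (length(labels) != length(edges) - 1L)
    stop("need one label per bin", call. = FALSE)
  structure(list(edges = edges, labels = labels), class = "group_spec")
}

#' Assign distress groups from VAS scores
#'
#' @param vas numeric VAS scores within the edge range.
#' @param spec a [group_spec()].
#' @return a factor with the spec's labels as levels.
#' @export
assign_groups <- function(vas, spec = group_spec()) {
  stopifnot(inherits(spec, "group_spec"))
  if (any(vas < spec$edges[1] | vas > spec$edges[length(spec$edges)]))
    stop("VAS score outside the edge range", call. = FALSE)
  idx <- findInterval(vas, spec$edges, rightmost.closed = TRUE)
  factor(spec$labels[idx], levels = spec$labels)
}

#' One-way ANOVA between two groups
#'
#' Classical equal-variance one-way ANOVA of an index between two groups.
#' With two groups the F statistic equals the square of the pooled-variance
#' two-sample t statistic and the p-values coincide.
#'
#' @param values numeric index values.
#' @param groups a two-level grouping factor (extra empty levels are
#'   dropped), each group with n >= 2.
#' @return named list `f`, `p`, `df1`, `df2`, `means` (named group means),
#'   `n` (named group sizes).
#' @export
anova_two_group <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L)
    stop("need exactly two non-empty groups", call. = FALSE)
  if (any(table(groups) < 2L))
    stop("each group needs n >= 2", call. = FALSE)
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(f = unname(ft$statistic), p = ft$p.value,
       df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]),
       means = c(tapply(values, groups, mean)),
       n = as.vector(table(groups)))
}

#' Expected orientation of an HRV index with respect to distress
#'
#' Higher distress lowers vagally mediated indices (mean RR, SDNN, RMSSD)
#' and raises the sympathovagal LF/HF ratio.
#'
#' @param index one of `"mean_rr"`, `"sdnn"`, `"rmssd"`, `"lf_hf"`.
#' @return `"low"` if low values indicate distress, else `"high"`.
#' @export
index_orientation <- function(index) {
  switch(match.arg(index, c("mean_rr", "sdnn", "rmssd", "lf_hf")),
         lf_hf = "high", "low")
}

#' ROC analysis of one HRV index for distress classification
#'
#' Builds the ROC curve of `values` for separating the positive (distressed)
#' class, with the index orientation fixed a priori by [index_orientation()]
#' (low values positive for mean RR / SDNN / RMSSD, high values positive for
#' LF/HF) rather than chosen from the data. Reports the area under the curve
#' and the top-left optimal threshold.
#'
#' @param values numeric index values.
#' @param positive logical (or 0/1) indicator of the distressed class; both
#'   classes must be present.
#' @param orientation `"low"` or `"high"`: which extreme indicates the
#'   positive class.
#' @return a list of class `roc_result`: `auc`, `threshold`, `sensitivity`,
#'   `specificity`, `curve` (tibble of `threshold`, `sensitivity`,
#'   `specificity`), `orientation`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(values, positive, orientation = c("low", "high")) {
  orientation <- match.arg(orientation)
  positive <- as.logical(positive)
  if (anyNA(values) || anyNA(positive)) stop("missing values", call. = FALSE)
  if (!any(positive) || all(positive))
    stop("need both classes present", call. = FALSE)
  direction <- if (orientation == "low") ">" else "<"  # pROC: controls vs cases
  roc <- pROC::roc(response = positive, predictor = values,
                   levels = c(FALSE, TRUE), direction = direction,
                   quiet = TRUE)
  cv <- pROC::coords(roc, "all", ret = c("threshold", "sensitivity",
                                         "specificity"), transpose = FALSE)
  curve <- tibble::tibble(threshold = cv$threshold,
                          sensitivity = cv$sensitivity,
                          specificity = cv$specificity)
  best <- topleft_threshold(curve)
  structure(list(auc = as.numeric(pROC::auc(roc)),
                 threshold = best$threshold,
                 sensitivity = best$sensitivity,
                 specificity = best$specificity,
                 curve = curve, orientation = orientation,
                 n_pos = sum(positive), n_neg = sum(!positive)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f | threshold %.4g (sens %.3f, spec %.3f) | %s positive | %d pos / %d neg\n",
    x$auc, x$threshold, x$sensitivity, x$specificity, x$orientation,
    x$n_pos, x$n_neg))
  invisible(x)
}

#' Top-left optimal operating point of a ROC curve
#'
#' The point minimising the squared distance to the top-left corner,
#' `(1 - sensitivity)^2 + (1 - specificity)^2`; ties break to the higher
#' sensitivity.
#'
#' @param curve a tibble with `threshold`, `sensitivity`, `specificity`.
#' @return the selected one-row tibble.
#' @export
topleft_threshold <- function(curve) {
  d2 <- (1 - curve$sensitivity)^2 + (1 - curve$specificity)^2
  cand <- which(d2 == min(d2))
  best <- cand[which.max(curve$sensitivity[cand])]
  curve[best, ]
}

#' Distress discrimination report
#'
#' For a study table: assigns VAS groups, then for each HRV index compares
#' the lowest and highest distress groups by two-group ANOVA and evaluates
#' the index as a classifier of the highest group against everyone else by
#' ROC analysis.
#'
#' @param study a [generate_study()]-shaped tibble with `vas` and
#'   `radar_<index>` columns.
#' @param indices character vector of index names.
#' @param spec a [group_spec()].
#' @return an object of class `distress_report`; [tidy()] returns the
#'   per-index tibble (`f`, `p`, `auc`, `threshold`, `sensitivity`,
#'   `specificity`), [glance()] a one-row summary. The `roc` element holds
#'   the full `roc_result` per index.
#' @export
distress_report <- function(study,
                            indices = c("mean_rr", "sdnn", "rmssd", "lf_hf"),
                            spec = group_spec()) {
  stopifnot(is.data.frame(study))
  grp <- assign_groups(study$vas, spec)
  lo <- spec$labels[1]
  hi <- spec$labels[length(spec$labels)]
  extreme <- grp %in% c(lo, hi)
  positive <- grp == hi
  rocs <- list()
  stats_tbl <- purrr::map_dfr(indices, function(j) {
    v <- study[[paste0("radar_", j)]]
    an <- anova_two_group(v[extreme], droplevels(grp[extreme]))
    rc <- roc_analysis(v, positive, orientation = index_orientation(j))
    rocs[[j]] <<- rc
    tibble::tibble(index = j, f = an$f, p = an$p,
                   mean_low = unname(an$means[lo]),
                   mean_high = unname(an$means[hi]),
                   auc = rc$auc, threshold = rc$threshold,
                   sensitivity = rc$sensitivity,
                   specificity = rc$specificity)
  })
  structure(list(stats = stats_tbl, roc = rocs, groups = grp,
                 indices = indices, spec = spec),
            class = "distress_report")
}

#' @export
print.distress_report <- function(x, ...) {
  cat(sprintf("<distress_report> %d participants (%s)\n",
              length(x$groups),
              paste(sprintf("%s %d", levels(x$groups), table(x$groups)),
                    collapse = ", ")))
  print(x$stats)
  invisible(x)
}

#' @rdname distress_report
#' @param x a `distress_report`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.distress_report <- function(x, ...) x$stats

#' @rdname distress_report
#' @exportS3Method generics::glance
glance.distress_report <- function(x, ...) {
  tibble::tibble(n = length(x$groups), n_indices = length(x$indices),
                 min_p = min(x$stats$p), max_auc = max(x$stats$auc))
}
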