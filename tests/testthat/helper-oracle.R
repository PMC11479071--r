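# Independent brute-force reference implementation of the peak detector:
# literal transcription of the amplitude-ordered suppression + window-max
# validation rule, written with different mechanics (explicit scalar loops,
# no vectorised tricks), so it cannot share a bug with detect_peaks().
brute_force_peaks <- function(v0, R, limit, strict = FALSE) {
  v <- v0
  n <- length(v0)
  cand_x <- integer(0)
  cand_y <- numeric(0)
  while (length(cand_x) < limit) {
    best <- 0
    best_i <- 0L
    for (i in seq_len(n)) {
      if (v[i] > best) { best <- v[i]; best_i <- i }
    }
    if (best <= 0) break
    cand_x <- c(cand_x, best_i)
    cand_y <- c(cand_y, best)
    for (i in seq_len(n)) {
      if (abs(i - best_i) <= R) v[i] <- 0
    }
  }
  keep <- logical(length(cand_x))
  for (j in seq_along(cand_x)) {
    wmax <- -Inf
    for (i in seq_len(n)) {
      if (abs(i - cand_x[j]) <= R && v0[i] > wmax) wmax <- v0[i]
    }
    keep[j] <- if (strict) cand_y[j] > wmax else cand_y[j] >= wmax
  }
  sort(cand_x[keep]) - 1L
}

# pair estimated RR intervals with ground-truth intervals by start time
match_rr <- function(est, truth_beats, tol_s = 0.1) {
  true_start <- truth_beats[-length(truth_beats)]
  true_iv <- diff(truth_beats) * 1000
  idx <- vapply(est$start_s, function(s) which.min(abs(true_start - s)),
                integer(1))
  ok <- abs(true_start[idx] - est$start_s) < tol_s & !duplicated(idx)
  list(est_ms = est$interval_ms[ok], true_ms = true_iv[idx[ok]],
       n_est = nrow(est), n_matched = sum(ok))
}
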