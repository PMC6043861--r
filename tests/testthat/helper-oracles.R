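# Independent brute-force oracles used by both the interval-selection
# unit tests and the end-to-end acceptance checks. These reimplement the
# scoring rules directly from their definitions (explicit refits, no
# shared code with the selectors).

# best RMSECV over 1..lv components on the given column set, via
# explicit per-fold refits
score_oracle <- function(X, y, cols, lv, asg) {
  folds <- sort(unique(asg))
  a_max <- min(lv, length(cols))  # sizes here never hit the sample bound
  pred <- matrix(NA_real_, nrow(X), a_max)
  for (f in folds) {
    te <- which(asg == f)
    for (a in seq_len(a_max)) {
      m <- suppressWarnings(fit_pls(X[-te, cols, drop = FALSE], y[-te], a))
      pred[te, a] <- predict(m, X[te, cols, drop = FALSE])
    }
  }
  min(sqrt(colMeans((pred - y)^2)))
}

# step-by-step transcription of the backward-elimination path: remove
# the interval whose omission scores best, record every stage, return
# the global optimum along the path
bipls_oracle <- function(X, y, grid, lv, asg, min_intervals = 1) {
  current <- seq_len(grid$n_intervals)
  path <- list(list(set = current,
                    score = score_oracle(X, y,
                                         interval_columns(grid, current),
                                         lv, asg)))
  while (length(current) > min_intervals) {
    sc <- vapply(seq_along(current), function(k)
      score_oracle(X, y, interval_columns(grid, current[-k]), lv, asg),
      numeric(1))
    k <- which.min(sc)
    current <- current[-k]
    path[[length(path) + 1L]] <- list(set = current, score = sc[k])
  }
  path[[which.min(vapply(path, `[[`, numeric(1), "score"))]]
}
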