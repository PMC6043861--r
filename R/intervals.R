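#' Equal-width interval grid over spectral variables
#'
#' Partitions `1..n_variables` into `n_intervals` contiguous,
#' non-overlapping intervals whose sizes differ by at most one; the
#' first `n_variables %% n_intervals` intervals carry the extra
#' variable.
#'
#' @param n_variables total variable count.
#' @param n_intervals interval count, `1 <= n_intervals <= n_variables`.
#' @return An object of class `interval_grid`: `n_intervals` and a data
#'   frame `boundaries` with inclusive 1-based `start`/`end` columns.
#' @export
make_grid <- function(n_variables, n_intervals) {
  n_variables <- as.integer(n_variables)
  n_intervals <- as.integer(n_intervals)
  if (n_intervals < 1L || n_intervals > n_variables)
    stop("need 1 <= n_intervals <= n_variables")
  base <- n_variables %/% n_intervals
  extra <- n_variables %% n_intervals
  sizes <- rep(base, n_intervals) + (seq_len(n_intervals) <= extra)
  end <- cumsum(sizes)
  structure(list(n_intervals = n_intervals, n_variables = n_variables,
                 boundaries = data.frame(start = end - sizes + 1L,
                                         end = end)),
            class = "interval_grid")
}

#' @export
print.interval_grid <- function(x, ...) {
  w <- unique(x$boundaries$end - x$boundaries$start + 1L)
  cat(sprintf("interval_grid: %d intervals over %d variables (width %s)\n",
              x$n_intervals, x$n_variables, paste(w, collapse = "/")))
  invisible(x)
}

#' Variable indices covered by a set of intervals
#'
#' @param grid an `interval_grid`.
#' @param selected integer vector of interval indices.
#' @return Sorted integer vector of variable (column) indices.
#' @export
interval_columns <- function(grid, selected) {
  b <- grid$boundaries
  sort(unlist(lapply(sort(selected),
                     function(i) b$start[i]:b$end[i])))
}

# build the interval_set result shared by the three selectors
.interval_set <- function(grid, selected, score, lv_used, selector) {
  selected <- sort(as.integer(selected))
  mask <- rep(FALSE, grid$n_variables)
  mask[interval_columns(grid, selected)] <- TRUE
  structure(list(grid = grid, selected = selected, variable_mask = mask,
                 score = score, lv_used = lv_used, selector = selector),
            class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("%s selection: interval(s) %s of %d (%d variables), RMSECV %.4g at %d LV\n",
              x$selector, paste(x$selected, collapse = ","),
              x$grid$n_intervals, sum(x$variable_mask), x$score, x$lv_used))
  invisible(x)
}

# RMSECV score of the model on a column subset: best error over factor
# counts 1..lv (clamped to what the subset supports), with the shared
# fold assignment. Returns c(score, lv_used).
.score_columns <- function(X, y, cols, lv, assignment) {
  Xs <- X[, cols, drop = FALSE]
  a_max <- min(lv, ncol(Xs), nrow(Xs) - 1L)
  cv <- cross_validate(Xs, y, max_lv = a_max, assignment = assignment)
  c(cv$rmsecv_by_lv[cv$best_lv], cv$best_lv)
}

# resolve the cv config (folds/seed/shuffle) into a fold assignment
.cv_assignment <- function(n, cv) {
  if (!is.null(cv$assignment)) return(cv$assignment)
  folds <- if (is.null(cv$folds)) 5L else cv$folds
  seed <- if (is.null(cv$seed)) 1L else cv$seed
  shuffle <- if (is.null(cv$shuffle)) TRUE else cv$shuffle
  fold_assignment(n, min(folds, n), seed, shuffle)
}

#' iPLS: best single interval
#'
#' Fits one PLS model per interval, on that interval's variables only,
#' scores each by RMSECV at up to `lv` latent factors, and returns the
#' interval with the lowest score (ties go to the lowest interval
#' index). All candidates share one cross-validation fold assignment.
#'
#' @param X training spectra matrix; `y` training reference values.
#' @param y numeric response vector.
#' @param grid an `interval_grid`.
#' @param lv latent-factor cap used when scoring.
#' @param cv cross-validation config: list with `folds` (default 5),
#'   `seed` (default 1), `shuffle` (default TRUE) or an explicit
#'   `assignment` vector.
#' @return An `interval_set` with a single selected interval.
#' @export
ipls_select <- function(X, y, grid, lv, cv = list()) {
  X <- as.matrix(X)
  assignment <- .cv_assignment(nrow(X), cv)
  sc <- vapply(seq_len(grid$n_intervals), function(i) {
    .score_columns(X, y, interval_columns(grid, i), lv, assignment)
  }, numeric(2))
  best <- which.min(sc[1, ])           # first minimum = lowest index on ties
  .interval_set(grid, best, sc[1, best], as.integer(sc[2, best]), "iPLS")
}

#' BiPLS: backward interval elimination
#'
#' Starts from all intervals and repeatedly removes the interval whose
#' omission gives the lowest RMSECV of the remaining set, recording the
#' score after every removal down to `min_intervals`; the interval set
#' with the global minimum RMSECV along the elimination path is
#' returned (the starting full set is a candidate too).
#'
#' @inheritParams ipls_select
#' @param min_intervals smallest set size considered (default 1).
#' @return An `interval_set`.
#' @export
bipls_select <- function(X, y, grid, lv, cv = list(), min_intervals = 1) {
  if (grid$n_intervals < 2L) stop("BiPLS needs at least 2 intervals")
  X <- as.matrix(X)
  assignment <- .cv_assignment(nrow(X), cv)
  current <- seq_len(grid$n_intervals)
  sc <- .score_columns(X, y, interval_columns(grid, current), lv, assignment)
  best <- list(selected = current, score = sc[1], lv_used = sc[2])
  while (length(current) > min_intervals) {
    cand <- vapply(seq_along(current), function(k) {
      keep <- current[-k]
      .score_columns(X, y, interval_columns(grid, keep), lv, assignment)
    }, numeric(2))
    k <- which.min(cand[1, ])          # ties: remove lowest-index interval
    current <- current[-k]
    if (cand[1, k] < best$score)
      best <- list(selected = current, score = cand[1, k],
                   lv_used = cand[2, k])
  }
  .interval_set(grid, best$selected, best$score,
                as.integer(best$lv_used), "BiPLS")
}

#' SiPLS: exhaustive interval-combination search
#'
#' Scores every combination of exactly `combo_size` intervals by the
#' RMSECV of a PLS model on their union and returns the best; ties go to
#' the lexicographically smallest index tuple (the enumeration order of
#' [utils::combn()]).
#'
#' @inheritParams ipls_select
#' @param combo_size number of intervals per combination.
#' @param max_combos guard on the combination count (default 10000);
#'   exceeded combinations raise an error advising fewer intervals.
#' @return An `interval_set` with `combo_size` selected intervals.
#' @export
sipls_select <- function(X, y, grid, lv, cv = list(), combo_size = 2,
                         max_combos = 10000) {
  combo_size <- as.integer(combo_size)
  if (combo_size < 1L || combo_size > grid$n_intervals)
    stop("combo_size must be in [1, n_intervals]")
  n_comb <- choose(grid$n_intervals, combo_size)
  if (n_comb > max_combos)
    stop(sprintf("%.0f combinations exceed the cap (%d); use fewer intervals or a smaller combo_size",
                 n_comb, max_combos))
  X <- as.matrix(X)
  assignment <- .cv_assignment(nrow(X), cv)
  combos <- utils::combn(grid$n_intervals, combo_size)
  sc <- apply(combos, 2, function(sel) {
    .score_columns(X, y, interval_columns(grid, sel), lv, assignment)
  })
  best <- which.min(sc[1, ])
  .interval_set(grid, combos[, best], sc[1, best],
                as.integer(sc[2, best]), "SiPLS")
}
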