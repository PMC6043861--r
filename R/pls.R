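#' NIPALS PLS1 regression
#'
#' Fits a single-response partial least squares model by NIPALS with mean
#' centering (no variance scaling — absorbance variables share a unit).
#' Per component `a`: the weight `w_a` is the unit-normalised covariance
#' direction `X'y`; the score is `t_a = X w_a`; the X-loading
#' `p_a = X't_a / t_a't_a` and y-loading `q_a = y't_a / t_a't_a`; then X
#' and y are deflated. The regression vector in centred variable space is
#' `b = W (P'W)^{-1} q`, so prediction is affine:
#' `yhat = (x - x_mean) b + y_mean`.
#'
#' If a component's weight vector has (numerically) zero norm the fit
#' stops early and returns a model with fewer components, flagged via
#' `$degenerate`, rather than erroring — a trajectory grid must survive
#' isolated degenerate fits.
#'
#' @param X numeric matrix, samples in rows.
#' @param y numeric response vector.
#' @param n_components number of latent factors, at most
#'   `min(nrow(X) - 1, ncol(X))`.
#' @return An object of class `pls_model`: `x_mean`, `y_mean`, `weights`
#'   `W`, `loadings` `P`, `y_loadings` `q`, `scores`, `coef` (regression
#'   vector for `n_components` factors), `coef_path` (one column per
#'   factor count `1..n_components`), `n_components`, `degenerate`.
#' @export
fit_pls <- function(X, y, n_components) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 samples")
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (stats::var(y) == 0) stop("response has zero variance")
  A <- as.integer(n_components)
  if (A < 1L) stop("n_components must be >= 1")
  if (A > min(n - 1L, p))
    stop(sprintf("n_components (%d) exceeds min(n_samples - 1, n_variables) = %d",
                 A, min(n - 1L, p)))
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean); yc <- y - y_mean
  W <- matrix(0, p, A); P <- matrix(0, p, A); Tm <- matrix(0, n, A)
  q <- numeric(A)
  tol <- 1e-12 * max(1, sqrt(sum(Xc^2)) * sqrt(sum(yc^2)))
  a <- 0L
  for (k in seq_len(A)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw <= tol) break
    w <- w / nw
    t_ <- drop(Xc %*% w)
    tt <- sum(t_^2)
    if (tt <= tol) break
    p_ <- drop(crossprod(Xc, t_)) / tt
    q_ <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - q_ * t_
    a <- k
    W[, k] <- w; P[, k] <- p_; Tm[, k] <- t_; q[k] <- q_
  }
  if (a == 0L) stop("no usable PLS component: X'y is numerically zero")
  degenerate <- a < A
  if (degenerate)
    warning(sprintf("deflation degenerate after %d of %d components; returning smaller model",
                    a, A))
  W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
  Tm <- Tm[, seq_len(a), drop = FALSE]; q <- q[seq_len(a)]
  # coefficient path: b_k for models truncated at 1..a components.
  # P'W is unit upper triangular, so R^{-1} comes from backsolve.
  R <- crossprod(P, W)
  coef_path <- matrix(0, p, a)
  for (k in seq_len(a)) {
    rk <- backsolve(R[seq_len(k), seq_len(k), drop = FALSE], q[seq_len(k)])
    coef_path[, k] <- W[, seq_len(k), drop = FALSE] %*% rk
  }
  structure(
    list(x_mean = x_mean, y_mean = y_mean, weights = W, loadings = P,
         y_loadings = q, scores = Tm, coef = coef_path[, a],
         coef_path = coef_path, n_components = a, degenerate = degenerate),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("NIPALS PLS1 model: %d latent factor%s, %d variables%s\n",
              x$n_components, if (x$n_components > 1) "s" else "",
              length(x$coef),
              if (x$degenerate) " (stopped early: degenerate deflation)" else ""))
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata numeric matrix (or single spectrum vector) with the
#'   same variable count as the fit.
#' @param ... unused.
#' @return Numeric vector of predictions, `(X - x_mean) b + y_mean`.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
    as.matrix(newdata)
  if (ncol(X) != length(object$coef))
    stop(sprintf("newdata has %d variables; model was fit on %d",
                 ncol(X), length(object$coef)))
  drop(sweep(X, 2L, object$x_mean) %*% object$coef) + object$y_mean
}

#' Cross-validated latent-factor selection
#'
#' k-fold cross-validation of NIPALS PLS1 over factor counts
#' `1..max_lv`. Fold assignment is either seeded-random (default) or
#' contiguous blocks; `folds = n` gives leave-one-out. The global RNG
#' state is left untouched.
#'
#' Folds whose training part supports fewer than `max_lv` components are
#' predicted at their largest feasible factor count for the missing
#' entries, so the error curve is always defined.
#'
#' @param X numeric matrix; `y` numeric response.
#' @param y numeric response vector.
#' @param max_lv largest factor count scored.
#' @param folds number of folds (>= 2, <= n).
#' @param seed integer seed for the random fold assignment.
#' @param shuffle logical; `FALSE` assigns contiguous blocks.
#' @param assignment optional explicit fold id per sample (overrides
#'   `folds`/`seed`/`shuffle`); used to share one assignment across many
#'   candidate models.
#' @return An object of class `cv_result`: `rmsecv_by_lv` (length
#'   `max_lv`), `best_lv` (argmin, first on ties), `assignment`.
#' @export
cross_validate <- function(X, y, max_lv, folds = 5, seed = 1,
                           shuffle = TRUE, assignment = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (is.null(assignment))
    assignment <- fold_assignment(n, folds, seed, shuffle)
  if (length(assignment) != n) stop("assignment length must equal nrow(X)")
  ids <- sort(unique(assignment))
  if (length(ids) < 2L) stop("need at least 2 folds")
  max_lv <- as.integer(max_lv)
  pred <- matrix(NA_real_, n, max_lv)
  for (f in ids) {
    te <- which(assignment == f); tr <- which(assignment != f)
    if (length(te) < 1L) stop("empty fold")
    a_max <- min(max_lv, length(tr) - 1L, ncol(X))
    fit <- suppressWarnings(fit_pls(X[tr, , drop = FALSE], y[tr], a_max))
    Xte <- sweep(X[te, , drop = FALSE], 2L, fit$x_mean)
    ph <- Xte %*% fit$coef_path + fit$y_mean   # n_te x a_fit
    a_fit <- fit$n_components
    pred[te, seq_len(a_fit)] <- ph
    if (a_fit < max_lv)
      pred[te, (a_fit + 1L):max_lv] <- ph[, a_fit]
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  structure(list(rmsecv_by_lv = rmsecv,
                 best_lv = which.min(rmsecv),
                 assignment = assignment),
            class = "cv_result")
}

#' Fold assignment for cross-validation
#'
#' @param n sample count.
#' @param folds fold count, `2 <= folds <= n`.
#' @param seed integer seed (random assignment only).
#' @param shuffle seeded-random assignment if `TRUE`, contiguous blocks
#'   if `FALSE`.
#' @return Integer vector of fold ids in `1..folds`, one per sample.
#' @export
fold_assignment <- function(n, folds, seed = 1, shuffle = TRUE) {
  folds <- as.integer(folds)
  if (folds < 2L || folds > n)
    stop("folds must satisfy 2 <= folds <= n")
  base <- rep(seq_len(folds), length.out = n)
  if (folds == n) return(seq_len(n))      # leave-one-out, order irrelevant
  if (!shuffle) return(sort(base))
  with_preserved_seed(seed, sample(base))
}

# run expr under set.seed(seed) without disturbing the caller's RNG
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cross-validation over %d latent factors: best = %d (RMSECV %.4g)\n",
              length(x$rmsecv_by_lv), x$best_lv,
              x$rmsecv_by_lv[x$best_lv]))
  invisible(x)
}
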