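#' Bagging configuration
#'
#' @param n_models ensemble size B (default 50).
#' @param resample_size bootstrap draw count per member; `NULL` (default)
#'   means the training-set size.
#' @param seed integer seed for the bootstrap draws.
#' @param aggregate `"mean"` (default) or `"median"` aggregation of
#'   member predictions.
#' @return An object of class `bagging_config`.
#' @export
bagging_config <- function(n_models = 50, resample_size = NULL, seed = 1,
                           aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  n_models <- as.integer(n_models)
  if (n_models < 1L) stop("n_models must be >= 1")
  if (!is.null(resample_size) && resample_size < 2)
    stop("resample_size must be >= 2")
  structure(list(n_models = n_models, resample_size = resample_size,
                 seed = as.integer(seed), aggregate = aggregate),
            class = "bagging_config")
}

#' Bagging-PLS: bootstrap-aggregated PLS1 ensemble
#'
#' Draws `B` bootstrap resamples of the training samples (with
#' replacement, seeded), fits one NIPALS PLS1 model per resample, and
#' predicts by aggregating member predictions (mean by default). A
#' resample whose response is constant cannot support a PLS fit and is
#' redrawn, up to a retry cap, so the ensemble always has exactly `B`
#' members.
#'
#' @param X training spectra matrix; `y` training reference values.
#' @param y numeric response vector.
#' @param n_components latent factors per member.
#' @param config a [bagging_config()].
#' @param indices optional list of `B` index vectors overriding the
#'   bootstrap draws (testing / reproduction hook); each member is then
#'   fit on exactly those rows.
#' @return An object of class `bagged_pls`: `members` (list of
#'   `pls_model`), `member_indices`, `config`, `n_components`.
#' @export
fit_bagging_pls <- function(X, y, n_components, config = bagging_config(),
                            indices = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  B <- config$n_models
  m <- if (is.null(config$resample_size)) n else as.integer(config$resample_size)
  if (is.null(indices)) {
    indices <- with_preserved_seed(config$seed, {
      out <- vector("list", B)
      retries <- 0L
      for (b in seq_len(B)) {
        repeat {
          idx <- sample.int(n, m, replace = TRUE)
          if (stats::var(y[idx]) > 0) break
          retries <- retries + 1L
          if (retries > 100L)
            stop("bootstrap retry cap exceeded: resampled response repeatedly constant")
        }
        out[[b]] <- idx
      }
      out
    })
  } else {
    if (length(indices) != B)
      stop("indices must be a list of length n_models")
  }
  members <- lapply(indices, function(idx) {
    Xb <- X[idx, , drop = FALSE]
    a <- min(n_components, length(idx) - 1L, ncol(X))
    suppressWarnings(fit_pls(Xb, y[idx], a))
  })
  structure(list(members = members, member_indices = indices,
                 config = config, n_components = n_components),
            class = "bagged_pls")
}

#' @export
print.bagged_pls <- function(x, ...) {
  cat(sprintf("Bagging-PLS ensemble: %d members, %d latent factors, %s aggregation\n",
              length(x$members), x$n_components, x$config$aggregate))
  invisible(x)
}

#' Predict from a Bagging-PLS ensemble
#'
#' @param object a `bagged_pls`.
#' @param newdata spectra matrix with the members' variable count.
#' @param ... unused.
#' @return Numeric vector: per-sample aggregate (mean or median, per the
#'   config) of the member predictions.
#' @export
predict.bagged_pls <- function(object, newdata, ...) {
  P <- member_predictions(object, newdata)
  if (object$config$aggregate == "mean") rowMeans(P)
  else apply(P, 1, stats::median)
}

#' Per-member predictions of a Bagging-PLS ensemble
#'
#' @param object a `bagged_pls`; `newdata` spectra matrix.
#' @param newdata spectra matrix with the members' variable count.
#' @return Matrix `n_samples x B` of member predictions.
#' @export
member_predictions <- function(object, newdata) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else
    as.matrix(newdata)
  P <- vapply(object$members, predict, numeric(nrow(X)), newdata = X)
  matrix(P, nrow = nrow(X))  # vapply drops dims when nrow(X) == 1
}
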