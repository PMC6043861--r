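#' Root mean square error of prediction
#'
#' `sqrt(mean((y_true - y_pred)^2))`. Named RMSEP when computed on a
#' validation set; the same formula on the training set is the RMSEC and
#' on pooled cross-validation residuals the RMSECV.
#'
#' @param y_true,y_pred numeric vectors of equal length (n >= 1).
#' @return Non-negative scalar in reference units.
#' @export
rmsep <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (length(y_true) < 1L) stop("need at least one value")
  sqrt(mean((y_true - y_pred)^2))
}

#' Ratio of performance to deviation (RPD)
#'
#' `sd(y_true) / rmsep(y_true, y_pred)` with the usual n-1 denominator
#' in the standard deviation. No bias correction is applied to the
#' prediction error (RMSEP, not SEP); see the package vignette for why
#' this convention was chosen. By construction
#' `rpd(y, yhat) * rmsep(y, yhat) == sd(y)` exactly.
#'
#' @param y_true,y_pred numeric vectors, `n >= 2`, `sd(y_true) > 0`.
#' @return Dimensionless scalar; `Inf` with a warning when the
#'   predictions are exact (zero RMSEP).
#' @export
rpd <- function(y_true, y_pred) {
  if (length(y_true) < 2L) stop("RPD needs at least 2 values")
  s <- stats::sd(y_true)
  if (s == 0) stop("reference values constant")
  e <- rmsep(y_true, y_pred)
  if (e == 0) {
    warning("perfect predictions: RMSEP is zero, RPD is infinite")
    return(Inf)
  }
  s / e
}

#' Classify an RPD value into quality bands
#'
#' Bands partition `[0, Inf)`: `poor` `[0, 2)`, `fair` `[2, 3)`, `good`
#' `[3, 3.5)`, `very_good` `[3.5, Inf)`. The boundary 3.5 belongs to
#' `very_good`.
#'
#' @param value non-negative RPD value(s); vectorised.
#' @return Character vector of band labels, with the band edges attached
#'   as attribute `"bounds"`.
#' @export
classify_rpd <- function(value) {
  if (any(value < 0)) stop("RPD must be non-negative")
  lab <- rpd_bands()$label
  out <- lab[findInterval(value, c(0, 2, 3, 3.5))]
  attr(out, "bounds") <- rpd_bands()
  out
}

#' RPD band definition
#'
#' @return Data frame of band labels with their lower (inclusive) and
#'   upper (exclusive) RPD edges.
#' @export
rpd_bands <- function() {
  data.frame(label = c("poor", "fair", "good", "very_good"),
             lower = c(0, 2, 3, 3.5),
             upper = c(2, 3, 3.5, Inf),
             stringsAsFactors = FALSE)
}

#' Validation metrics for a prediction
#'
#' @param y_true,y_pred numeric vectors (validation reference values and
#'   predictions).
#' @return An object of class `evaluation_metrics`: `rmsep`, `rpd`, `r2`
#'   (coefficient of determination), `n`.
#' @export
evaluate_predictions <- function(y_true, y_pred) {
  e <- rmsep(y_true, y_pred)
  r <- rpd(y_true, y_pred)
  sst <- sum((y_true - mean(y_true))^2)
  structure(list(rmsep = e, rpd = r,
                 r2 = 1 - sum((y_true - y_pred)^2) / sst,
                 n = length(y_true)),
            class = "evaluation_metrics")
}

#' @export
print.evaluation_metrics <- function(x, ...) {
  cat(sprintf("RMSEP %.4g | RPD %.4g (%s) | R2 %.4g | n = %d\n",
              x$rmsep, x$rpd, classify_rpd(min(x$rpd, 1e12))[1], x$r2, x$n))
  invisible(x)
}
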