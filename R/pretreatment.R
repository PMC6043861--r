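#' Pretreatment specification
#'
#' The four pretreatments used along a processing trajectory: raw
#' passthrough, Savitzky-Golay smoothing, and Savitzky-Golay first and
#' second derivatives. Derivatives are implemented as SG derivative
#' filters (not finite differences) so the whole family shares one
#' noise-robust local-polynomial construction.
#'
#' @param method one of `"raw"`, `"sg_smooth"`, `"derivative_1"`,
#'   `"derivative_2"`.
#' @param window odd filter window length in points (default 9).
#' @param poly_order local polynomial degree (default 2); must be smaller
#'   than `window` and at least the derivative order.
#' @return An object of class `pretreatment_spec`.
#' @export
pretreatment_spec <- function(method = c("raw", "sg_smooth",
                                         "derivative_1", "derivative_2"),
                              window = 9, poly_order = 2) {
  method <- match.arg(method)
  deriv <- switch(method, raw = 0L, sg_smooth = 0L,
                  derivative_1 = 1L, derivative_2 = 2L)
  window <- as.integer(window)
  poly_order <- as.integer(poly_order)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3")
  if (poly_order >= window)
    stop("poly_order must be smaller than window")
  if (poly_order < deriv)
    stop(sprintf("poly_order (%d) must be >= derivative order (%d)",
                 poly_order, deriv))
  structure(list(method = method, window = window,
                 poly_order = poly_order, deriv = deriv),
            class = "pretreatment_spec")
}

#' @export
print.pretreatment_spec <- function(x, ...) {
  if (x$method == "raw") cat("pretreatment: raw (identity)\n")
  else cat(sprintf("pretreatment: %s, window %d, polynomial order %d\n",
                   x$method, x$window, x$poly_order))
  invisible(x)
}

#' Parse a short pretreatment label
#'
#' Convenience mapping of the labels used on the trajectory grid:
#' `"raw"`, `"d1"` (SG first derivative), `"d2"` (SG second derivative),
#' `"sg9"` (9-point SG smoothing). A `pretreatment_spec` passes through
#' unchanged.
#'
#' @param x label or `pretreatment_spec`.
#' @return A `pretreatment_spec`.
#' @export
as_pretreatment <- function(x) {
  if (inherits(x, "pretreatment_spec")) return(x)
  switch(as.character(x),
         raw = pretreatment_spec("raw"),
         d1 = pretreatment_spec("derivative_1"),
         d2 = pretreatment_spec("derivative_2"),
         sg9 = pretreatment_spec("sg_smooth", window = 9),
         stop(sprintf("unknown pretreatment label '%s'", x)))
}

#' Savitzky-Golay convolution kernel
#'
#' Coefficients of the least-squares local-polynomial filter: fitting a
#' degree-`poly_order` polynomial to `window` consecutive points and
#' evaluating its `deriv`-th derivative at the window centre is a linear
#' map, and these are its weights. Smoothing kernels (`deriv = 0`) sum to
#' 1; derivative kernels sum to 0.
#'
#' The derivative is taken with respect to the point index (unit
#' spacing); no rescaling by axis spacing is applied.
#'
#' @param window odd window length, >= 3.
#' @param poly_order polynomial degree, `< window`.
#' @param deriv derivative order, `<= poly_order`.
#' @return Numeric vector of `window` convolution coefficients `c` such
#'   that the filtered value at point `j` is
#'   `sum(c * x[(j-h):(j+h)])` with `h = (window-1)/2`.
#' @export
sg_kernel <- function(window, poly_order, deriv = 0) {
  window <- as.integer(window); poly_order <- as.integer(poly_order)
  deriv <- as.integer(deriv)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3")
  if (poly_order < 0L || poly_order >= window)
    stop("poly_order must be in [0, window)")
  if (deriv < 0L || deriv > poly_order)
    stop("deriv must be in [0, poly_order]")
  h <- (window - 1L) %/% 2L
  .sg_row(z = seq(-h, h), poly_order = poly_order, deriv = deriv)
}

# weights of the least-squares polynomial fit over points at offsets `z`,
# evaluating the deriv-th derivative of the fit at the centre (offset 0):
# only the degree-`deriv` coefficient survives, scaled by deriv!
.sg_row <- function(z, poly_order, deriv) {
  V <- outer(z, 0:poly_order, `^`)
  G <- solve(crossprod(V), t(V))          # (p+1) x m: data -> coefficients
  factorial(deriv) * G[deriv + 1L, ]
}

#' Apply a spectral pretreatment
#'
#' Filters every spectrum independently. Output length equals input
#' length: interior points use the full symmetric SG kernel; near the
#' edges the window shrinks to the largest symmetric window that fits
#' (with the polynomial degree capped at the available point count minus
#' one), so interval indices stay aligned across pretreatments. The axis
#' and reference values pass through unchanged.
#'
#' @param ds a `spectral_dataset`.
#' @param spec a `pretreatment_spec` (or label accepted by
#'   [as_pretreatment()]).
#' @return The pretreated `spectral_dataset`.
#' @export
apply_pretreatment <- function(ds, spec) {
  stopifnot(inherits(ds, "spectral_dataset"))
  spec <- as_pretreatment(spec)
  if (spec$method == "raw") return(ds)
  X <- filter_matrix(ds$spectra, spec$window, spec$poly_order, spec$deriv)
  spectral_dataset(X, ds$axis, ds$reference, ds$axis_unit,
                   ds$reference_unit, ds$sample_ids)
}

# SG-filter the rows of X (n_samples x n_vars), shrink-window edges
filter_matrix <- function(X, window, poly_order, deriv) {
  p <- ncol(X)
  if (window > p)
    stop(sprintf("window (%d) exceeds number of variables (%d)", window, p))
  h <- (window - 1L) %/% 2L
  k <- sg_kernel(window, poly_order, deriv)
  out <- matrix(0, nrow(X), p)
  # interior: position j takes columns (j-h)..(j+h)
  if (p >= window) {
    interior <- (h + 1L):(p - h)
    # build via accumulation: out[, j] = sum_i k[i] * X[, j - h - 1 + i]
    for (i in seq_len(window)) {
      cols <- interior - h - 1L + i
      out[, interior] <- out[, interior] +
        k[i] * X[, cols, drop = FALSE]
    }
  }
  # edges: shrink to largest centred window, cap degree at points - 1
  for (j in seq_len(h)) {
    for (side in c("left", "right")) {
      jj <- if (side == "left") j else p - j + 1L
      hj <- j - 1L
      m <- 2L * hj + 1L
      pj <- min(poly_order, m - 1L)
      val <- if (pj < deriv) {
        rep(0, nrow(X))  # derivative order exceeds the fit degree
      } else {
        kj <- .sg_row(seq(-hj, hj), pj, deriv)
        drop(X[, (jj - hj):(jj + hj), drop = FALSE] %*% kj)
      }
      out[, jj] <- val
    }
  }
  out
}
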