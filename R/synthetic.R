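#' Specification of a synthetic NIR-like dataset
#'
#' Defines a Beer-Lambert linear mixture: each pure component contributes
#' one or more Gaussian absorption bands on the spectral axis, sample
#' spectra are concentration-weighted sums of the pure spectra plus a
#' smooth polynomial baseline and additive i.i.d. Gaussian noise, and
#' component 1 is the regressand analyte.
#'
#' @param n_samples,n_variables dataset shape.
#' @param axis numeric spectral axis (length `n_variables`), strictly
#'   monotone.
#' @param bands data frame with columns `center` (axis position), `width`
#'   (Gaussian sigma, axis units) and `component` (1-based component
#'   index); every component must own at least one band.
#' @param conc_range matrix (or 2-vector recycled) with one row per
#'   component giving the uniform concentration range `[lo, hi]`.
#' @param band_height peak absorbance of a unit-concentration band
#'   (default 1 AU).
#' @param baseline_degree,baseline_amplitude per-sample random polynomial
#'   baseline: degree (default 1) and coefficient amplitude in AU
#'   (default 0 = no baseline).
#' @param noise_sd standard deviation of the additive noise, AU.
#' @param seed integer seed; generation is fully reproducible.
#' @param axis_unit,reference_unit units carried into the dataset.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples, n_variables, axis, bands,
                           conc_range, band_height = 1,
                           baseline_degree = 1, baseline_amplitude = 0,
                           noise_sd = 0, seed = 1,
                           axis_unit = c("cm-1", "nm"),
                           reference_unit = "") {
  axis_unit <- match.arg(axis_unit)
  bands <- as.data.frame(bands)
  stopifnot(all(c("center", "width", "component") %in% names(bands)))
  if (length(axis) != n_variables)
    stop("axis length must equal n_variables")
  rng <- range(axis)
  if (any(bands$center < rng[1] | bands$center > rng[2]))
    stop("band centers must lie within the axis")
  k <- max(bands$component)
  if (!setequal(unique(bands$component), seq_len(k)))
    stop("every component in 1..max(component) needs at least one band")
  if (is.null(dim(conc_range)))
    conc_range <- matrix(rep(as.numeric(conc_range), k),
                         ncol = 2, byrow = TRUE)
  conc_range <- as.matrix(conc_range)
  if (nrow(conc_range) != k || ncol(conc_range) != 2)
    stop("conc_range must give one [lo, hi] row per component")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 n_variables = as.integer(n_variables),
                 axis = as.numeric(axis), bands = bands,
                 n_components = k, conc_range = conc_range,
                 band_height = band_height,
                 baseline_degree = as.integer(baseline_degree),
                 baseline_amplitude = baseline_amplitude,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 axis_unit = axis_unit, reference_unit = reference_unit),
            class = "synthetic_spec")
}

#' Generate a synthetic spectral dataset
#'
#' Draws concentrations `C` uniformly per component, builds pure spectra
#' `S` as sums of Gaussian bands, and returns
#' `X = C S + baseline + noise` as a [spectral_dataset()] whose
#' reference vector is the analyte (component 1) concentration.
#'
#' @param spec a [synthetic_spec()].
#' @param seed optional seed overriding `spec$seed`.
#' @return List with `dataset` (a `spectral_dataset`), `concentrations`
#'   (matrix `n_samples x n_components`) and `pure_spectra` (matrix
#'   `n_components x n_variables`).
#' @export
generate_synthetic <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(seed)) seed <- spec$seed
  n <- spec$n_samples; p <- spec$n_variables; k <- spec$n_components
  S <- matrix(0, k, p)
  for (i in seq_len(nrow(spec$bands))) {
    b <- spec$bands[i, ]
    S[b$component, ] <- S[b$component, ] +
      spec$band_height * exp(-0.5 * ((spec$axis - b$center) / b$width)^2)
  }
  out <- with_preserved_seed(seed, {
    C <- vapply(seq_len(k), function(j)
      stats::runif(n, spec$conc_range[j, 1], spec$conc_range[j, 2]),
      numeric(n))
    C <- matrix(C, nrow = n)
    X <- C %*% S
    if (spec$baseline_amplitude > 0) {
      u <- seq(-1, 1, length.out = p)
      Bco <- matrix(stats::runif(n * (spec$baseline_degree + 1L),
                                 -spec$baseline_amplitude,
                                 spec$baseline_amplitude), nrow = n)
      X <- X + Bco %*% t(outer(u, 0:spec$baseline_degree, `^`))
    }
    if (spec$noise_sd > 0)
      X <- X + matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
    list(C = C, X = X)
  })
  ds <- spectral_dataset(out$X, spec$axis, out$C[, 1], spec$axis_unit,
                         spec$reference_unit)
  list(dataset = ds, concentrations = out$C, pure_spectra = S)
}

#' Synthetic analogue of the pharmaceutical tablet dataset
#'
#' A 310-sample, 404-variable transmittance-like dataset on a
#' 7,000-10,500 cm-1 wavenumber axis with four broad bands near 10,000,
#' 8,830, 8,200 and 7,840 cm-1, one band per mixture component; the
#' analyte emulates an active ingredient varying over 5-10 % w/w
#' against three excipient components, with mild baseline drift and
#' noise at about 1 % of peak absorbance.
#'
#' @param seed integer seed.
#' @param noise_sd noise standard deviation, AU.
#' @return A [synthetic_spec()].
#' @export
synthetic_tablet_spec <- function(seed = 1, noise_sd = 0.01) {
  axis <- seq(7000, 10500, length.out = 404)
  bands <- data.frame(
    center = c(10000, 8830, 8200, 7840),
    width = c(260, 220, 180, 150),
    component = 1:4)
  synthetic_spec(310, 404, axis, bands,
                 conc_range = rbind(c(0.05, 0.10), c(0.3, 0.7),
                                    c(0.2, 0.6), c(0.1, 0.5)),
                 band_height = 1, baseline_degree = 1,
                 baseline_amplitude = 0.02, noise_sd = noise_sd,
                 seed = seed, axis_unit = "cm-1", reference_unit = "%w/w")
}

#' Synthetic analogue of the Lonicera japonica process dataset
#'
#' A 216-sample, 2,800-variable dataset on a 1,100-2,500 nm wavelength
#' axis; the analyte emulates chlorogenic acid (0.1-1 mg/mL) among four
#' matrix components, with informative bands inside the 1,100-1,900 nm
#' window typically retained for modeling and strong uninformative
#' structure above it.
#'
#' @param seed integer seed.
#' @param noise_sd noise standard deviation, AU.
#' @return A [synthetic_spec()].
#' @export
synthetic_lonicera_spec <- function(seed = 1, noise_sd = 0.01) {
  axis <- seq(1100, 2500, length.out = 2800)
  bands <- data.frame(
    center = c(1450, 1690, 1200, 1790, 2100, 2350),
    width = c(45, 60, 50, 55, 80, 70),
    component = c(1, 1, 2, 3, 4, 4))
  synthetic_spec(216, 2800, axis, bands,
                 conc_range = rbind(c(0.1, 1.0), c(0.5, 1.5),
                                    c(0.3, 1.2), c(0.5, 2.0)),
                 band_height = 1, baseline_degree = 1,
                 baseline_amplitude = 0.02, noise_sd = noise_sd,
                 seed = seed, axis_unit = "nm",
                 reference_unit = "mg/mL")
}
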