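# Toy data builders shared across the suite. Everything is generated in
# code, seeded, and small.

# plain dataset on an integer axis with random spectra
toy_dataset <- function(n = 8, p = 12, seed = 1) {
  set.seed(seed)
  spectral_dataset(matrix(rnorm(n * p), n, p), axis = seq_len(p),
                   reference = runif(n), axis_unit = "nm")
}

# interval-structured data: columns of the informative interval(s) carry
# a Gaussian band profile scaled by y; all other columns are pure noise.
# Signal bands themselves are noise-free unless signal_noise > 0.
make_band_data <- function(n = 50, p = 100, n_intervals = 10,
                           informative = 3, seed = 1, noise_sd = 0.2,
                           signal_noise = 0) {
  set.seed(seed)
  grid <- make_grid(p, n_intervals)
  y <- runif(n, 1, 2)
  X <- matrix(rnorm(n * p, sd = noise_sd), n, p)
  for (iv in informative) {
    cols <- interval_columns(grid, iv)
    ctr <- mean(cols)
    shape <- exp(-0.5 * ((cols - ctr) / (length(cols) / 4))^2)
    X[, cols] <- outer(y, shape) +
      matrix(rnorm(n * length(cols), sd = signal_noise), n)
  }
  list(X = X, y = y, grid = grid)
}

# noiseless linear mixture with a known regression structure
noiseless_mixture <- function(n = 30, p = 40, k = 2, seed = 1) {
  set.seed(seed)
  S <- matrix(0, k, p)
  for (j in seq_len(k))
    S[j, ] <- exp(-0.5 * ((seq_len(p) - p * j / (k + 1)) / (p / 12))^2)
  C <- matrix(runif(n * k, 0.5, 1.5), n, k)
  list(X = C %*% S, y = C[, 1], C = C, S = S)
}

# small synthetic_spec for trajectory-level tests
small_synth_spec <- function(seed = 1, n = 80, p = 60, noise_sd = 0.01) {
  synthetic_spec(
    n, p, axis = seq_len(p),
    bands = data.frame(center = c(p * 0.25, p * 0.7),
                       width = c(p / 18, p / 14), component = 1:2),
    conc_range = rbind(c(0.5, 1.5), c(0.5, 1.5)),
    baseline_amplitude = 0.01, noise_sd = noise_sd, seed = seed,
    axis_unit = "nm")
}

small_config <- function(seed = 1, ...) {
  trajectory_config(pretreatments = c("raw", "sg9"),
                    selectors = c("iPLS", "BiPLS"),
                    lv = c(2, 3), methods = c("PLS", "BaggingPLS"),
                    n_intervals = 6, combo_size = 2,
                    bagging = bagging_config(n_models = 8),
                    seed = seed, ...)
}
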