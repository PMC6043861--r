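#' Construct a spectral dataset
#'
#' A `spectral_dataset` bundles an absorbance matrix (one row per sample,
#' one column per spectral variable), the ordered spectral axis those
#' columns live on, and a single reference value per sample (the analyte
#' content the calibration predicts).
#'
#' @param spectra numeric matrix, `n_samples x n_variables`, absorbance (AU).
#' @param axis numeric vector of axis positions, strictly monotone
#'   (increasing or decreasing), length equal to `ncol(spectra)`.
#' @param reference numeric vector of analyte reference values, one per
#'   sample.
#' @param axis_unit axis unit, `"cm-1"` (wavenumber) or `"nm"` (wavelength).
#' @param reference_unit free-text unit of the reference values, e.g.
#'   `"%w/w"` or `"mg/mL"`.
#' @param sample_ids optional character vector of sample identifiers;
#'   defaults to `"s1", "s2", ...`.
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(spectra, axis, reference,
                             axis_unit = c("cm-1", "nm"),
                             reference_unit = "",
                             sample_ids = NULL) {
  axis_unit <- match.arg(axis_unit)
  spectra <- as.matrix(spectra)
  storage.mode(spectra) <- "double"
  axis <- as.numeric(axis)
  reference <- as.numeric(reference)
  if (length(axis) < 2L)
    stop("spectral axis must have at least 2 points")
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0)))
    stop("spectral axis must be strictly monotone")
  if (ncol(spectra) != length(axis))
    stop(sprintf("axis length (%d) does not match number of variables (%d)",
                 length(axis), ncol(spectra)))
  if (nrow(spectra) != length(reference))
    stop(sprintf("reference length (%d) does not match number of samples (%d)",
                 length(reference), nrow(spectra)))
  if (anyNA(spectra) || anyNA(axis) || anyNA(reference))
    stop("dataset contains missing values")
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(spectra)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(spectra))
    stop("sample_ids length does not match number of samples")
  dimnames(spectra) <- NULL
  structure(
    list(spectra = spectra, axis = axis, axis_unit = axis_unit,
         reference = reference, reference_unit = reference_unit,
         sample_ids = sample_ids),
    class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("spectral_dataset: %d samples x %d variables\n",
              nrow(x$spectra), ncol(x$spectra)))
  cat(sprintf("  axis: %g to %g %s\n", x$axis[1],
              x$axis[length(x$axis)], x$axis_unit))
  cat(sprintf("  reference: %g to %g %s\n", min(x$reference),
              max(x$reference),
              if (nzchar(x$reference_unit)) x$reference_unit else "(no unit)"))
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$spectra)

#' Subset a spectral dataset by sample
#'
#' @param ds a `spectral_dataset`.
#' @param i integer sample indices.
#' @return A `spectral_dataset` with the selected samples, in the given
#'   order.
#' @export
subset_samples <- function(ds, i) {
  stopifnot(inherits(ds, "spectral_dataset"))
  spectral_dataset(ds$spectra[i, , drop = FALSE], ds$axis,
                   ds$reference[i], ds$axis_unit, ds$reference_unit,
                   ds$sample_ids[i])
}

#' Read a spectral dataset from delimited text
#'
#' Expects one row per sample and a single header row: the reference
#' column is named (`reference_col`), an optional sample-id column is
#' named (`id_col`), and every remaining column name must parse as a
#' number — those names are the spectral axis positions.
#'
#' @param path path to the delimited text file.
#' @param reference_col name of the reference-value column.
#' @param axis_unit axis unit, `"cm-1"` or `"nm"`.
#' @param id_col name of the sample-id column, or `NULL` if absent.
#' @param reference_unit unit string stored with the reference values.
#' @param sep field delimiter (default comma).
#' @return A validated `spectral_dataset`; row order is preserved.
#' @export
read_dataset <- function(path, reference_col = "reference",
                         axis_unit = c("cm-1", "nm"), id_col = "sample_id",
                         reference_unit = "", sep = ",") {
  axis_unit <- match.arg(axis_unit)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!reference_col %in% names(df))
    stop(sprintf("reference column '%s' not found in '%s'",
                 reference_col, path))
  ids <- NULL
  if (!is.null(id_col) && id_col %in% names(df)) {
    ids <- df[[id_col]]
    df[[id_col]] <- NULL
  }
  reference <- .parse_numeric_column(df[[reference_col]], reference_col)
  df[[reference_col]] <- NULL
  axis <- suppressWarnings(as.numeric(names(df)))
  if (anyNA(axis))
    stop(sprintf("non-numeric axis header(s): %s",
                 paste(names(df)[is.na(axis)][1:min(3, sum(is.na(axis)))],
                       collapse = ", ")))
  spectra <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df))
  for (j in seq_along(df))
    spectra[, j] <- .parse_numeric_column(df[[j]], names(df)[j])
  spectral_dataset(spectra, axis, reference, axis_unit, reference_unit,
                   sample_ids = ids)
}

.parse_numeric_column <- function(x, name) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                 x[bad[1]], bad[1], name))
  v
}

#' Write a spectral dataset to delimited text
#'
#' Inverse of [read_dataset()]: one header row carrying the sample-id and
#' reference column names plus the numeric axis positions, one row per
#' sample.
#'
#' @param ds a `spectral_dataset`.
#' @param path output file path.
#' @param reference_col,id_col column names used in the header.
#' @param sep field delimiter.
#' @param digits significant digits written (default 15, enough for exact
#'   double round-trip of typical absorbance values).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, reference_col = "reference",
                          id_col = "sample_id", sep = ",", digits = 15) {
  stopifnot(inherits(ds, "spectral_dataset"))
  df <- data.frame(ds$sample_ids,
                   format(ds$reference, digits = digits, trim = TRUE),
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, reference_col)
  sp <- apply(ds$spectra, 2, format, digits = digits, trim = TRUE)
  sp <- matrix(sp, nrow = nrow(ds$spectra))
  colnames(sp) <- format(ds$axis, digits = digits, trim = TRUE)
  out <- cbind(df, sp)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Crop a spectral dataset to an axis region
#'
#' Keeps exactly the variables whose axis position `p` satisfies
#' `lo <= p <= hi` (closed interval), regardless of axis direction.
#'
#' @param ds a `spectral_dataset`.
#' @param lo,hi region bounds in axis units, `lo < hi`.
#' @return The cropped `spectral_dataset`.
#' @export
crop_region <- function(ds, lo, hi) {
  stopifnot(inherits(ds, "spectral_dataset"))
  if (!(lo < hi)) stop("crop region requires lo < hi")
  keep <- ds$axis >= lo & ds$axis <= hi
  if (!any(keep)) stop("region excludes all variables")
  spectral_dataset(ds$spectra[, keep, drop = FALSE], ds$axis[keep],
                   ds$reference, ds$axis_unit, ds$reference_unit,
                   ds$sample_ids)
}

#' Kennard-Stone sample set partitioning
#'
#' Deterministic greedy max-min selection on Euclidean distance between
#' (raw, un-pretreated) spectra: the two mutually most distant samples
#' seed the training set, then the sample whose minimum distance to the
#' already-selected set is largest is added until `n_train` samples are
#' selected. Ties are broken by lowest sample index, so the split is
#' fully deterministic.
#'
#' @param ds a `spectral_dataset`.
#' @param n_train number of training samples, `2 <= n_train < n_samples`.
#' @return A list of class `split_result` with elements `train` and
#'   `validation` (both `spectral_dataset`), `train_indices` (in selection
#'   order) and `validation_indices` (ascending).
#' @export
kennard_stone_split <- function(ds, n_train) {
  stopifnot(inherits(ds, "spectral_dataset"))
  n <- nrow(ds$spectra)
  if (n_train < 2 || n_train >= n)
    stop("n_train must satisfy 2 <= n_train < n_samples")
  D <- as.matrix(stats::dist(ds$spectra))
  dimnames(D) <- NULL
  # seed pair: lexicographically smallest among the most distant pairs
  m <- max(D)
  hits <- which(D == m, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  sel <- as.integer(hits[1, ])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < n_train) {
    nxt <- which.max(mind)  # which.max returns the first (lowest-index) max
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  val <- setdiff(seq_len(n), sel)
  structure(
    list(train = subset_samples(ds, sel),
         validation = subset_samples(ds, val),
         train_indices = sel, validation_indices = val),
    class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("Kennard-Stone split: %d train / %d validation samples\n",
              length(x$train_indices), length(x$validation_indices)))
  invisible(x)
}
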