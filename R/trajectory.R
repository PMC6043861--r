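#' Trajectory configuration
#'
#' Defines the four grid axes of a processing trajectory — pretreatment,
#' variable selector, latent-factor count, calibration method — plus the
#' shared settings (interval grid, cross-validation scheme, bagging
#' ensemble, master seed) every path uses.
#'
#' @param pretreatments labels or `pretreatment_spec`s: any of `"raw"`,
#'   `"d1"`, `"d2"`, `"sg9"`.
#' @param selectors any of `"none"` (full spectrum), `"iPLS"`, `"BiPLS"`,
#'   `"SiPLS"`.
#' @param lv integer vector of latent-factor counts (default 1:10).
#' @param methods any of `"PLS"`, `"BaggingPLS"`.
#' @param n_intervals interval-grid size for the selectors (default 20).
#' @param combo_size SiPLS combination size (default 2).
#' @param min_intervals BiPLS stopping size (default 1).
#' @param cv_folds,cv_shuffle cross-validation scheme used by selectors
#'   and the stepwise optimizer (default 5 shuffled folds).
#' @param bagging a [bagging_config()] shared by all Bagging-PLS paths;
#'   its `seed` field is ignored — member draws are seeded from `seed`
#'   and the path's own spec so that a given spec always yields the same
#'   model wherever it is evaluated.
#' @param max_combos SiPLS combination cap.
#' @param seed master seed: fixes the fold assignment and all bootstrap
#'   draws, making a whole trajectory report reproducible.
#' @return An object of class `trajectory_config`.
#' @export
trajectory_config <- function(pretreatments = c("raw", "d1", "d2", "sg9"),
                              selectors = c("iPLS", "BiPLS", "SiPLS"),
                              lv = 1:10,
                              methods = c("PLS", "BaggingPLS"),
                              n_intervals = 20, combo_size = 2,
                              min_intervals = 1,
                              cv_folds = 5, cv_shuffle = TRUE,
                              bagging = bagging_config(),
                              max_combos = 10000, seed = 1) {
  selectors <- match.arg(selectors, c("none", "iPLS", "BiPLS", "SiPLS"),
                         several.ok = TRUE)
  methods <- match.arg(methods, c("PLS", "BaggingPLS"), several.ok = TRUE)
  if (!length(pretreatments) || !length(lv))
    stop("every grid axis must be non-empty")
  lv <- as.integer(lv)
  if (any(lv < 1L)) stop("latent-factor counts must be >= 1")
  structure(list(pretreatments = pretreatments, selectors = selectors,
                 lv = lv, methods = methods,
                 n_intervals = as.integer(n_intervals),
                 combo_size = as.integer(combo_size),
                 min_intervals = as.integer(min_intervals),
                 cv_folds = as.integer(cv_folds), cv_shuffle = cv_shuffle,
                 bagging = bagging, max_combos = max_combos,
                 seed = as.integer(seed)),
            class = "trajectory_config")
}

.pretreat_label <- function(x) {
  if (inherits(x, "pretreatment_spec"))
    switch(x$method, raw = "raw", derivative_1 = "d1",
           derivative_2 = "d2",
           sg_smooth = sprintf("sg%d", x$window))
  else as.character(x)
}

#' One point of the trajectory grid
#'
#' @param pretreatment pretreatment label or `pretreatment_spec`.
#' @param selector `"none"`, `"iPLS"`, `"BiPLS"` or `"SiPLS"`.
#' @param lv latent-factor count.
#' @param method `"PLS"` or `"BaggingPLS"`.
#' @return An object of class `path_spec`.
#' @export
path_spec <- function(pretreatment, selector, lv, method) {
  selector <- match.arg(selector, c("none", "iPLS", "BiPLS", "SiPLS"))
  method <- match.arg(method, c("PLS", "BaggingPLS"))
  structure(list(pretreatment = pretreatment, selector = selector,
                 lv = as.integer(lv), method = method),
            class = "path_spec")
}

#' @export
print.path_spec <- function(x, ...) {
  cat(sprintf("path: %s | %s | %d LV | %s\n", .pretreat_label(x$pretreatment),
              x$selector, x$lv, x$method))
  invisible(x)
}

#' Enumerate all paths of a trajectory grid
#'
#' Full Cartesian product of the four axes in deterministic
#' pretreatment-major order (pretreatment, then selector, then latent
#' factors, then method).
#'
#' @param config a [trajectory_config()].
#' @return List of [path_spec()] objects; length is the product of the
#'   axis sizes.
#' @export
enumerate_paths <- function(config) {
  stopifnot(inherits(config, "trajectory_config"))
  out <- list()
  for (pre in config$pretreatments)
    for (sel in config$selectors)
      for (l in config$lv)
        for (m in config$methods)
          out[[length(out) + 1L]] <- path_spec(pre, sel, l, m)
  out
}

# deterministic 31-bit seed from the master seed and a path spec, so an
# identical spec gets identical randomness wherever it is evaluated
.spec_seed <- function(base, spec) {
  s <- paste(.pretreat_label(spec$pretreatment), spec$selector, spec$lv,
             spec$method, sep = "|")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 1048573
  as.integer((abs(base) %% 1021) * 1048573 + h) %% 2147483647L
}

.traj_cv <- function(config, n) {
  list(assignment = fold_assignment(n, min(config$cv_folds, n),
                                    config$seed, config$cv_shuffle))
}

# run (and cache) the variable selection for one (pretreatment, selector,
# lv) cell on the pretreated training data
.select_variables <- function(Xt, y, spec, config, cache = NULL) {
  if (spec$selector == "none") return(NULL)
  key <- paste(.pretreat_label(spec$pretreatment), spec$selector, spec$lv,
               sep = "|")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  grid <- make_grid(ncol(Xt), min(config$n_intervals, ncol(Xt)))
  cv <- .traj_cv(config, nrow(Xt))
  sel <- switch(spec$selector,
    iPLS = ipls_select(Xt, y, grid, spec$lv, cv),
    BiPLS = bipls_select(Xt, y, grid, spec$lv, cv,
                         min_intervals = config$min_intervals),
    SiPLS = sipls_select(Xt, y, grid, spec$lv, cv,
                         combo_size = min(config$combo_size,
                                          grid$n_intervals),
                         max_combos = config$max_combos))
  if (!is.null(cache)) cache[[key]] <- sel
  sel
}

#' Evaluate one modeling path
#'
#' Runs the fixed pipeline: pretreat both sets, select variables on the
#' training set only, fit the calibration method on the training set at
#' the path's latent-factor count, predict the validation set, and
#' compute RMSEP/RPD with the RPD band. Validation data never touch
#' selection or fitting. A selector or fit failure yields a failed
#' `path_result` (with the reason) rather than an error, so a grid run
#' survives isolated numerical failures.
#'
#' @param train,validation `spectral_dataset`s sharing an axis.
#' @param spec a [path_spec()].
#' @param config a [trajectory_config()] supplying the shared settings.
#' @param cache optional environment caching selections across the
#'   method/LV axes (as [run_trajectory()] does).
#' @return An object of class `path_result`: `spec`, `ok`, `metrics`
#'   (an `evaluation_metrics` or `NULL`), `rpd_class`, `interval_set`
#'   (`NULL` marks full spectrum), `lv_fitted`, `seed`, `reason`.
#' @export
run_path <- function(train, validation, spec, config = trajectory_config(),
                     cache = NULL) {
  stopifnot(inherits(spec, "path_spec"))
  if (!isTRUE(all.equal(train$axis, validation$axis)))
    stop("train and validation must share the spectral axis")
  seed <- .spec_seed(config$seed, spec)
  fail <- function(reason)
    structure(list(spec = spec, ok = FALSE, metrics = NULL,
                   rpd_class = NA_character_, interval_set = NULL,
                   lv_fitted = NA_integer_, seed = seed, reason = reason),
              class = "path_result")
  tryCatch({
    pre <- as_pretreatment(spec$pretreatment)
    tr <- apply_pretreatment(train, pre)
    va <- apply_pretreatment(validation, pre)
    sel <- .select_variables(tr$spectra, tr$reference, spec, config, cache)
    cols <- if (is.null(sel)) seq_len(ncol(tr$spectra)) else
      which(sel$variable_mask)
    Xtr <- tr$spectra[, cols, drop = FALSE]
    Xva <- va$spectra[, cols, drop = FALSE]
    a <- min(spec$lv, ncol(Xtr), nrow(Xtr) - 1L)
    model <- if (spec$method == "PLS") {
      suppressWarnings(fit_pls(Xtr, tr$reference, a))
    } else {
      bc <- config$bagging
      bc$seed <- seed
      fit_bagging_pls(Xtr, tr$reference, a, bc)
    }
    yhat <- predict(model, Xva)
    met <- evaluate_predictions(va$reference, yhat)
    structure(list(spec = spec, ok = TRUE, metrics = met,
                   rpd_class = as.character(classify_rpd(met$rpd)),
                   interval_set = sel,
                   lv_fitted = a, seed = seed, reason = NA_character_),
              class = "path_result")
  }, error = function(e) fail(conditionMessage(e)))
}

#' @export
print.path_result <- function(x, ...) {
  print(x$spec)
  if (x$ok) {
    cat("  "); print(x$metrics)
  } else cat(sprintf("  FAILED: %s\n", x$reason))
  invisible(x)
}

#' Run a full processing trajectory
#'
#' Evaluates every path of the configured grid on a training/validation
#' split, classifies each by its RPD band, tallies the bands, identifies
#' the best path (highest RPD; ties broken by lower RMSEP, then
#' enumeration order) and embeds the one-factor-at-a-time stepwise
#' baseline for comparison. Selections are cached per (pretreatment,
#' selector, latent-factor) cell so the method axis reuses them.
#'
#' @param train,validation `spectral_dataset`s from one split (e.g.
#'   [kennard_stone_split()]).
#' @param config a [trajectory_config()].
#' @param stepwise include the stepwise baseline (default TRUE).
#' @return An object of class `trajectory_report`: `results` (list of
#'   `path_result` in enumeration order), `table` (one row per path, see
#'   [as.data.frame.trajectory_report()]), `class_counts` (named tally
#'   over RPD bands plus `failed`, summing to the path count), `best`,
#'   `stepwise_baseline`, `config`, `provenance`.
#' @export
run_trajectory <- function(train, validation, config = trajectory_config(),
                           stepwise = TRUE) {
  specs <- enumerate_paths(config)
  cache <- new.env(parent = emptyenv())
  results <- lapply(specs, function(s)
    run_path(train, validation, s, config, cache))
  tab <- .results_table(results)
  bands <- c(rpd_bands()$label, "failed")
  cls <- ifelse(tab$ok, tab$rpd_class, "failed")
  class_counts <- stats::setNames(
    vapply(bands, function(b) sum(cls == b), integer(1)), bands)
  best <- .best_result(results)
  sw <- if (stepwise)
    stepwise_optimize(train, validation, config, cache = cache) else NULL
  structure(
    list(results = results, table = tab, class_counts = class_counts,
         best = best, stepwise_baseline = sw, config = config,
         provenance = list(
           n_train = nrow(train$spectra),
           n_validation = nrow(validation$spectra),
           n_variables = ncol(train$spectra),
           train_checksum = .dataset_checksum(train),
           validation_checksum = .dataset_checksum(validation),
           seed = config$seed)),
    class = "trajectory_report")
}

.dataset_checksum <- function(ds) {
  sprintf("%dx%d:%.10e:%.10e", nrow(ds$spectra), ncol(ds$spectra),
          sum(ds$spectra), sum(ds$reference))
}

.results_table <- function(results) {
  do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(
      path = i,
      pretreatment = .pretreat_label(r$spec$pretreatment),
      selector = r$spec$selector, lv = r$spec$lv,
      method = r$spec$method, ok = r$ok,
      rmsep = if (r$ok) r$metrics$rmsep else NA_real_,
      rpd = if (r$ok) r$metrics$rpd else NA_real_,
      r2 = if (r$ok) r$metrics$r2 else NA_real_,
      rpd_class = r$rpd_class,
      lv_fitted = r$lv_fitted,
      n_selected = if (is.null(r$interval_set)) NA_integer_ else
        sum(r$interval_set$variable_mask),
      intervals = if (is.null(r$interval_set)) "full" else
        paste(r$interval_set$selected, collapse = ","),
      reason = r$reason,
      stringsAsFactors = FALSE)
  }))
}

.best_result <- function(results) {
  ok <- Filter(function(r) r$ok, results)
  if (!length(ok)) return(NULL)
  rpds <- vapply(ok, function(r) r$metrics$rpd, numeric(1))
  top <- which(rpds == max(rpds))
  if (length(top) > 1L) {
    rms <- vapply(ok[top], function(r) r$metrics$rmsep, numeric(1))
    top <- top[rms == min(rms)]
  }
  ok[[top[1]]]   # remaining ties: enumeration order
}

#' Path table of a trajectory report
#'
#' @param x a `trajectory_report`.
#' @param ... unused.
#' @return Data frame with one row per evaluated path: the four grid
#'   coordinates, RMSEP/RPD/R2, the RPD band, the fitted factor count,
#'   the selected intervals and variable count (`"full"` for
#'   full-spectrum paths), and the failure reason where a path failed.
#' @export
as.data.frame.trajectory_report <- function(x, ...) x$table

#' @export
print.trajectory_report <- function(x, ...) {
  cat(sprintf("trajectory_report: %d paths (%d train / %d validation samples)\n",
              length(x$results), x$provenance$n_train,
              x$provenance$n_validation))
  cat("  RPD bands:",
      paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
            collapse = "  "), "\n")
  if (!is.null(x$best)) {
    cat("  best "); print(x$best$spec)
    cat("    "); print(x$best$metrics)
  }
  if (!is.null(x$stepwise_baseline) && x$stepwise_baseline$ok) {
    cat("  stepwise baseline "); print(x$stepwise_baseline$spec)
    cat("    "); print(x$stepwise_baseline$metrics)
  }
  invisible(x)
}

#' Plot RPD (or RMSEP) against latent factors per pretreatment/selector
#'
#' Simple base-graphics panels, one per pretreatment x selector cell,
#' with one line per calibration method.
#'
#' @param x a `trajectory_report`.
#' @param metric `"rpd"` or `"rmsep"`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.trajectory_report <- function(x, metric = c("rpd", "rmsep"), ...) {
  metric <- match.arg(metric)
  tab <- x$table[x$table$ok, ]
  pres <- unique(tab$pretreatment); sels <- unique(tab$selector)
  op <- graphics::par(mfrow = c(length(pres), length(sels)),
                      mar = c(3.5, 3.5, 1.5, 0.5), mgp = c(2, 0.7, 0))
  on.exit(graphics::par(op))
  for (p in pres) for (s in sels) {
    cell <- tab[tab$pretreatment == p & tab$selector == s, ]
    wide <- stats::reshape(cell[, c("lv", "method", metric)],
                           idvar = "lv", timevar = "method",
                           direction = "wide")
    wide <- wide[order(wide$lv), , drop = FALSE]
    graphics::matplot(wide$lv, as.matrix(wide[, -1, drop = FALSE]),
                      type = "b", pch = 1:2, lty = 1,
                      xlab = "latent factors", ylab = toupper(metric),
                      main = paste(p, s, sep = " / "), ...)
  }
  invisible(x)
}

#' One-factor-at-a-time stepwise optimization (the conventional baseline)
#'
#' The conventional alternative to an exhaustive trajectory: start from
#' defaults (raw spectra, no variable selection, latent factors at the
#' cross-validation minimum, plain PLS) and optimize one factor at a
#' time by validation RMSEP — first the pretreatment, then the variable
#' selector, then the latent-factor count over the configured grid, and
#' finally the calibration method. The returned result is the final
#' path's `path_result`; because the final path lies on the trajectory
#' grid, its RPD can never exceed the exhaustive trajectory's best
#' (greedy search visits a subset of the grid).
#'
#' @inheritParams run_trajectory
#' @param cache optional selection cache shared with [run_trajectory()].
#' @return A `path_result` for the stepwise-optimized path.
#' @export
stepwise_optimize <- function(train, validation, config = trajectory_config(),
                              cache = NULL) {
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  lv_grid <- sort(config$lv)
  clamp_lv <- function(l) max(min(l, max(lv_grid)), min(lv_grid))
  assignment <- .traj_cv(config, nrow(train$spectra))$assignment
  cv_lv <- function(pre) {
    tr <- apply_pretreatment(train, as_pretreatment(pre))
    a_max <- min(max(lv_grid), ncol(tr$spectra), nrow(tr$spectra) - 1L)
    clamp_lv(cross_validate(tr$spectra, tr$reference, a_max,
                            assignment = assignment)$best_lv)
  }
  eval_rmsep <- function(r) if (r$ok) r$metrics$rmsep else Inf
  # step 1: pretreatment (selector "none", LV at the CV minimum, PLS)
  step1 <- lapply(config$pretreatments, function(pre)
    run_path(train, validation,
             path_spec(pre, "none", cv_lv(pre), "PLS"), config, cache))
  pre <- config$pretreatments[[which.min(vapply(step1, eval_rmsep,
                                                numeric(1)))]]
  lv0 <- cv_lv(pre)
  # step 2: variable selector, holding the pretreatment
  step2 <- lapply(config$selectors, function(s)
    run_path(train, validation, path_spec(pre, s, lv0, "PLS"),
             config, cache))
  sel <- config$selectors[[which.min(vapply(step2, eval_rmsep,
                                            numeric(1)))]]
  # step 3: latent factors over the configured grid
  step3 <- lapply(lv_grid, function(l)
    run_path(train, validation, path_spec(pre, sel, l, "PLS"),
             config, cache))
  lv <- lv_grid[[which.min(vapply(step3, eval_rmsep, numeric(1)))]]
  # step 4: calibration method
  step4 <- lapply(config$methods, function(m)
    run_path(train, validation, path_spec(pre, sel, lv, m),
             config, cache))
  step4[[which.min(vapply(step4, eval_rmsep, numeric(1)))]]
}

#' Write a trajectory report to disk
#'
#' Writes the per-path table as tab-delimited text
#' (`<dir>/paths.tsv`), the report summary (band counts, best path,
#' stepwise baseline, provenance) as JSON (`<dir>/report.json`), and
#' RPD/RMSEP-vs-LV panel plots as PDFs when requested.
#'
#' @param report a `trajectory_report`.
#' @param dir output directory (created if needed).
#' @param plots also write the panel plots (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, plots = TRUE) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_report requires the jsonlite package")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$table, file.path(dir, "paths.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  path_line <- function(r) if (is.null(r) || !r$ok) NULL else list(
    pretreatment = .pretreat_label(r$spec$pretreatment),
    selector = r$spec$selector, lv = r$spec$lv, method = r$spec$method,
    rmsep = r$metrics$rmsep, rpd = r$metrics$rpd, rpd_class = r$rpd_class)
  jsonlite::write_json(
    list(n_paths = length(report$results),
         class_counts = as.list(report$class_counts),
         best = path_line(report$best),
         stepwise_baseline = path_line(report$stepwise_baseline),
         provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  if (plots) {
    for (m in c("rpd", "rmsep")) {
      grDevices::pdf(file.path(dir, paste0(m, "_vs_lv.pdf")), 10, 8)
      plot(report, metric = m)
      grDevices::dev.off()
    }
  }
  invisible(dir)
}
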