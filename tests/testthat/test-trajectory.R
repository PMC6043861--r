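test_that("path enumeration is the Cartesian product in pretreatment-major order", {
  cfg <- trajectory_config()  # 4 pretreatments x 3 selectors x 10 LV x 2 methods
  paths <- enumerate_paths(cfg)
  expect_length(paths, 240)
  labs <- vapply(paths, function(s)
    paste(s$pretreatment, s$selector, s$lv, s$method, sep = "|"),
    character(1))
  expect_equal(anyDuplicated(labs), 0L)
  expect_equal(labs[1], "raw|iPLS|1|PLS")
  expect_equal(labs[2], "raw|iPLS|1|BaggingPLS")
  expect_equal(labs[3], "raw|iPLS|2|PLS")
  expect_equal(labs[240], "sg9|SiPLS|10|BaggingPLS")
  # adding the full-spectrum arm multiplies the count by 4/3
  cfg4 <- trajectory_config(selectors = c("none", "iPLS", "BiPLS", "SiPLS"))
  expect_length(enumerate_paths(cfg4), 320)
  single <- trajectory_config(pretreatments = "raw", selectors = "iPLS",
                              lv = 3, methods = "PLS")
  expect_length(enumerate_paths(single), 1)
  expect_error(trajectory_config(pretreatments = character(0)), "non-empty")
})

test_that("a selector-free PLS path is exactly pretreat + fit + evaluate", {
  g <- generate_synthetic(small_synth_spec(seed = 2))
  sp <- kennard_stone_split(g$dataset, 55)
  cfg <- small_config(seed = 3)
  r <- run_path(sp$train, sp$validation,
                path_spec("sg9", "none", 3, "PLS"), cfg)
  tr <- apply_pretreatment(sp$train, "sg9")
  va <- apply_pretreatment(sp$validation, "sg9")
  m <- fit_pls(tr$spectra, tr$reference, 3)
  met <- evaluate_predictions(va$reference, predict(m, va$spectra))
  expect_true(r$ok)
  expect_null(r$interval_set)
  expect_equal(r$metrics$rmsep, met$rmsep, tolerance = 1e-12)
  expect_equal(r$metrics$rpd, met$rpd, tolerance = 1e-12)
  expect_equal(r$rpd_class, as.character(classify_rpd(met$rpd)))
})

test_that("a failing path is reported, not raised", {
  ds <- toy_dataset(10, 20, seed = 1)
  ds$reference <- rep(1, 10)  # constant response: PLS cannot fit
  sp <- list(train = subset_samples(ds, 1:7),
             validation = subset_samples(ds, 8:10))
  r <- run_path(sp$train, sp$validation, path_spec("raw", "none", 2, "PLS"),
                small_config())
  expect_false(r$ok)
  expect_match(r$reason, "variance")
  expect_true(is.null(r$metrics))
})

test_that("trajectory reports keep exact books on a small grid", {
  g <- generate_synthetic(small_synth_spec(seed = 4, noise_sd = 0.05))
  sp <- kennard_stone_split(g$dataset, 55)
  cfg <- trajectory_config(pretreatments = c("raw", "sg9"),
                           selectors = c("iPLS", "BiPLS"), lv = c(2, 3),
                           methods = "PLS", n_intervals = 5, seed = 6)
  rep1 <- run_trajectory(sp$train, sp$validation, cfg)
  expect_length(rep1$results, 8)
  expect_equal(nrow(rep1$table), 8L)
  expect_equal(sum(rep1$class_counts), 8)
  expect_equal(unname(rep1$class_counts["failed"]), 0L)
  # class counts agree with per-path classification
  expect_equal(unname(rep1$class_counts[rep1$best$rpd_class]) >= 1, TRUE)
  # best path dominates every row and the tie-break is by RMSEP
  expect_true(all(rep1$table$rpd <= rep1$best$metrics$rpd))
  # re-running the best spec in isolation reproduces its metrics exactly
  iso <- run_path(sp$train, sp$validation, rep1$best$spec, cfg)
  expect_equal(iso$metrics, rep1$best$metrics)
  # and the whole report is deterministic
  rep2 <- run_trajectory(sp$train, sp$validation, cfg)
  expect_identical(rep1$table, rep2$table)
})

test_that("the stepwise baseline never beats the exhaustive trajectory", {
  for (s in 1:6) {
    g <- generate_synthetic(small_synth_spec(seed = s, noise_sd = 0.04))
    sp <- kennard_stone_split(g$dataset, 55)
    cfg <- small_config(seed = s)
    rep <- run_trajectory(sp$train, sp$validation, cfg)
    expect_true(rep$stepwise_baseline$ok)
    expect_lte(rep$stepwise_baseline$metrics$rpd, rep$best$metrics$rpd)
  }
})

test_that("a singleton grid makes the stepwise optimizer equal the only path", {
  g <- generate_synthetic(small_synth_spec(seed = 8))
  sp <- kennard_stone_split(g$dataset, 55)
  cfg <- trajectory_config(pretreatments = "sg9", selectors = "iPLS",
                           lv = 3, methods = "PLS", n_intervals = 5,
                           seed = 2)
  sw <- stepwise_optimize(sp$train, sp$validation, cfg)
  direct <- run_path(sp$train, sp$validation,
                     path_spec("sg9", "iPLS", 3, "PLS"), cfg)
  expect_equal(sw$metrics, direct$metrics)
  expect_equal(sw$spec, direct$spec)
})

test_that("validation data influence metrics but never selection or coefficients", {
  g <- generate_synthetic(small_synth_spec(seed = 9, noise_sd = 0.03))
  sp <- kennard_stone_split(g$dataset, 55)
  cfg <- small_config(seed = 1)
  spec <- path_spec("raw", "iPLS", 3, "PLS")
  r1 <- run_path(sp$train, sp$validation, spec, cfg)
  vperturb <- sp$validation
  vperturb$reference <- vperturb$reference + 0.1
  r2 <- run_path(sp$train, vperturb, spec, cfg)
  expect_identical(r2$interval_set$selected, r1$interval_set$selected)
  expect_identical(r2$interval_set$score, r1$interval_set$score)
  expect_false(isTRUE(all.equal(r1$metrics$rmsep, r2$metrics$rmsep)))
})

test_that("an informative band ends up in the best path's selection across seeds", {
  hits <- vapply(1:10, function(s) {
    d <- make_band_data(n = 60, p = 60, n_intervals = 6, informative = 3,
                        seed = s, noise_sd = 0.3, signal_noise = 0.05)
    ds <- spectral_dataset(d$X, seq_len(60), d$y, axis_unit = "nm")
    sp <- kennard_stone_split(ds, 40)
    cfg <- trajectory_config(pretreatments = "raw",
                             selectors = c("iPLS", "SiPLS"), lv = c(1, 2),
                             methods = "PLS", n_intervals = 6, seed = s)
    rep <- run_trajectory(sp$train, sp$validation, cfg, stepwise = FALSE)
    3 %in% rep$best$interval_set$selected
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("reports serialize to a path table and JSON summary", {
  g <- generate_synthetic(small_synth_spec(seed = 10))
  sp <- kennard_stone_split(g$dataset, 55)
  cfg <- trajectory_config(pretreatments = "raw", selectors = "iPLS",
                           lv = 2:3, methods = "PLS", n_intervals = 5,
                           seed = 1)
  rep <- run_trajectory(sp$train, sp$validation, cfg)
  dir <- withr::local_tempdir()
  write_report(rep, dir, plots = FALSE)
  tab <- read.delim(file.path(dir, "paths.tsv"))
  expect_equal(nrow(tab), 2L)
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$n_paths, 2L)
  expect_equal(js$best$rpd, rep$best$metrics$rpd)
  expect_equal(sum(unlist(js$class_counts)), 2L)
})
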