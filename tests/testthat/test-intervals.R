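test_that("equal-width grids spread the remainder over the first intervals", {
  g <- make_grid(404, 20)
  w <- g$boundaries$end - g$boundaries$start + 1L
  expect_equal(sum(w == 21), 4)
  expect_equal(sum(w == 20), 16)
  expect_equal(w[1:4], rep(21L, 4))
  expect_equal(sum(w), 404)
  expect_equal(g$boundaries$start[1], 1L)
  expect_equal(g$boundaries$end[20], 404L)
  g1 <- make_grid(10, 1)
  expect_equal(as.integer(unlist(g1$boundaries)), c(1L, 10L))
  gs <- make_grid(5, 5)
  expect_equal(gs$boundaries$start, 1:5)
  expect_equal(gs$boundaries$end, 1:5)
  expect_error(make_grid(5, 6), "n_intervals")
})

test_that("iPLS matches exhaustive per-interval scoring and recovers the informative band", {
  d <- make_band_data(n = 40, p = 48, n_intervals = 4, informative = 2,
                      seed = 1)
  asg <- fold_assignment(40, 5, seed = 7)
  sel <- ipls_select(d$X, d$y, d$grid, lv = 3, cv = list(assignment = asg))
  scores <- vapply(1:4, function(i)
    score_oracle(d$X, d$y, interval_columns(d$grid, i), 3, asg), numeric(1))
  expect_equal(sel$selected, which.min(scores))
  expect_equal(sel$score, min(scores), tolerance = 1e-12)
  # only band 3 of 10 covaries with y
  d2 <- make_band_data(n = 50, p = 100, n_intervals = 10, informative = 3,
                       seed = 2)
  sel2 <- ipls_select(d2$X, d2$y, d2$grid, lv = 2,
                      cv = list(folds = 5, seed = 1))
  expect_equal(sel2$selected, 3L)
  # degenerate one-interval grid scores the full spectrum
  g1 <- make_grid(100, 1)
  asg2 <- fold_assignment(50, 5, seed = 1)
  sel3 <- ipls_select(d2$X, d2$y, g1, lv = 2, cv = list(assignment = asg2))
  expect_equal(sel3$selected, 1L)
  expect_equal(sel3$score, score_oracle(d2$X, d2$y, 1:100, 2, asg2),
               tolerance = 1e-12)
})

test_that("SiPLS matches exhaustive enumeration and recovers informative pairs", {
  d <- make_band_data(n = 40, p = 50, n_intervals = 5,
                      informative = c(2, 4), seed = 3)
  asg <- fold_assignment(40, 4, seed = 5)
  sel <- sipls_select(d$X, d$y, d$grid, lv = 3,
                      cv = list(assignment = asg), combo_size = 2)
  combos <- combn(5, 2)
  scores <- apply(combos, 2, function(sset)
    score_oracle(d$X, d$y, interval_columns(d$grid, sset), 3, asg))
  expect_equal(sel$selected, sort(combos[, which.min(scores)]))
  expect_equal(sel$score, min(scores), tolerance = 1e-12)
  # two informative bands among 6 intervals
  d2 <- make_band_data(n = 50, p = 90, n_intervals = 6,
                       informative = c(1, 5), seed = 4)
  sel2 <- sipls_select(d2$X, d2$y, d2$grid, lv = 3,
                       cv = list(folds = 5, seed = 1), combo_size = 2)
  expect_equal(sel2$selected, c(1L, 5L))
  # combo_size = n_intervals is the full spectrum
  asg2 <- fold_assignment(50, 5, seed = 1)
  self <- sipls_select(d2$X, d2$y, d2$grid, lv = 2,
                       cv = list(assignment = asg2), combo_size = 6)
  expect_equal(self$selected, 1:6)
  expect_equal(self$score, score_oracle(d2$X, d2$y, 1:90, 2, asg2),
               tolerance = 1e-12)
  expect_error(sipls_select(d2$X, d2$y, d2$grid, lv = 2, combo_size = 3,
                            max_combos = 10), "cap")
})

test_that("SiPLS with singleton combinations is exactly iPLS", {
  d <- make_band_data(n = 45, p = 60, n_intervals = 6, informative = 4,
                      seed = 6)
  cv <- list(folds = 5, seed = 9)
  a <- ipls_select(d$X, d$y, d$grid, lv = 3, cv = cv)
  b <- sipls_select(d$X, d$y, d$grid, lv = 3, cv = cv, combo_size = 1)
  expect_equal(b$selected, a$selected)
  expect_equal(b$score, a$score)
  expect_equal(b$lv_used, a$lv_used)
})

test_that("BiPLS follows the greedy elimination path and keeps informative intervals", {
  d <- make_band_data(n = 40, p = 50, n_intervals = 5,
                      informative = c(2, 5), seed = 7)
  asg <- fold_assignment(40, 4, seed = 3)
  sel <- bipls_select(d$X, d$y, d$grid, lv = 3, cv = list(assignment = asg))
  orc <- bipls_oracle(d$X, d$y, d$grid, 3, asg)
  expect_equal(sel$selected, sort(orc$set))
  expect_equal(sel$score, orc$score, tolerance = 1e-12)
  # two informative + two pure-noise intervals
  d2 <- make_band_data(n = 50, p = 80, n_intervals = 4,
                       informative = c(1, 3), seed = 8)
  sel2 <- bipls_select(d2$X, d2$y, d2$grid, lv = 3,
                       cv = list(folds = 5, seed = 1))
  expect_true(all(c(1, 3) %in% sel2$selected))
  expect_false(any(c(2, 4) %in% sel2$selected))
  # 2-interval grid considers both singletons and the full pair
  d3 <- make_band_data(n = 30, p = 20, n_intervals = 2, informative = 1,
                       seed = 9)
  asg3 <- fold_assignment(30, 5, seed = 2)
  sel3 <- bipls_select(d3$X, d3$y, d3$grid, lv = 2,
                       cv = list(assignment = asg3))
  cand <- list(1:2, 1L, 2L)
  scores <- vapply(cand, function(sset)
    score_oracle(d3$X, d3$y, interval_columns(d3$grid, sset), 2, asg3),
    numeric(1))
  # greedy explores the full set plus the better elimination branch;
  # its winner can never beat the exhaustive optimum and must be one of
  # the candidates
  expect_true(sel3$score >= min(scores) - 1e-12)
  expect_true(any(vapply(cand, identical, logical(1),
                         as.integer(sel3$selected))))
  # min_intervals = n_intervals returns the full set
  sel4 <- bipls_select(d3$X, d3$y, d3$grid, lv = 2,
                       cv = list(assignment = asg3), min_intervals = 2)
  expect_equal(sel4$selected, 1:2)
})

test_that("interval sets are internally consistent and seeded-deterministic", {
  d <- make_band_data(n = 40, p = 60, n_intervals = 6,
                      informative = c(2, 6), seed = 10)
  cv <- list(folds = 5, seed = 4)
  for (fn in list(ipls_select, bipls_select,
                  function(...) sipls_select(..., combo_size = 2))) {
    s1 <- fn(d$X, d$y, d$grid, 3, cv)
    s2 <- fn(d$X, d$y, d$grid, 3, cv)
    expect_identical(s1, s2)
    expect_gte(s1$score, 0)
    expect_equal(sum(s1$variable_mask),
                 length(interval_columns(d$grid, s1$selected)))
    expect_equal(which(s1$variable_mask),
                 interval_columns(d$grid, s1$selected))
    expect_true(s1$lv_used >= 1 && s1$lv_used <= 3)
  }
})
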