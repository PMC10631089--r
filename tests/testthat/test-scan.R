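test_that("the log likelihood ratio matches direct evaluation of the closed form", {
  ct <- tiny_table()
  # hand evaluation: 9 log .9 + 1 log .1 + 5 log .5 + 5 log .5
  #                  - (14 log .7 + 6 log .3)
  expect_equal(llr_multinomial(1, ct), 2.034984501583937, tolerance = 1e-12)
  # complement symmetry on a 2-region table
  expect_equal(llr_multinomial(1, ct), llr_multinomial(2, ct))
})

test_that("llr is zero when inside and outside category proportions agree", {
  map <- grid_geography(3)
  ct <- uniform_table(map, per_cell = 3)
  for (win in list(1L, c(1L, 2L), 1:4))
    expect_equal(llr_multinomial(win, ct), 0)
})

test_that("llr is invariant to category relabelling and complementation", {
  set.seed(5)
  for (i in 1:10) {
    X <- matrix(rpois(6 * 4, 4), 6, 4)
    X[1, ] <- X[1, ] + 1      # guarantee a nonempty table
    ct <- case_table(X)
    win <- sort(sample(6, sample(2:4, 1)))
    comp <- setdiff(1:6, win)
    perm <- sample(4)
    ct_perm <- case_table(X[, perm])
    expect_equal(llr_multinomial(win, ct), llr_multinomial(win, ct_perm))
    expect_equal(llr_multinomial(win, ct), llr_multinomial(comp, ct))
    expect_gte(llr_multinomial(win, ct), 0)
  }
})

test_that("relative risks follow the inside/outside share ratio", {
  ct <- tiny_table()
  expect_equal(relative_risks(1, ct), c(1.8, 0.2))
  map <- grid_geography(3)
  expect_equal(relative_risks(c(1L, 5L), uniform_table(map)), rep(1, 4))
  # a category absent inside the window reports risk 0
  X <- matrix(c(5, 5, 0, 5), 2, 2)
  expect_equal(relative_risks(1, case_table(X))[2], 0)
  expect_error(relative_risks(1:2, tiny_table()), "all cases")
})

test_that("the vectorised window kernel agrees with the scalar formula", {
  map <- grid_geography(3)
  set.seed(21)
  ct <- case_table(matrix(rpois(9 * 4, 3) + 1, 9, 4), map = map)
  w <- enumerate_windows(map, ct)
  fit <- multinom_scan(ct, windows = w, R = 5, seed = 9)
  ref <- vapply(w$sets, llr_multinomial, numeric(1), cases = ct)
  expect_equal(fit$llr, ref, tolerance = 1e-10)
  # the most likely cluster attains the maximum over all candidates
  expect_equal(fit$llr[fit$ranked[1]], max(ref))
})

test_that("null randomisation preserves both margins exactly", {
  set.seed(31)
  rows <- c(4, 0, 7, 9); cols <- c(6, 6, 8)
  tabs <- r2dtable(50, rows, cols)
  for (tb in tabs) {
    expect_equal(rowSums(tb), rows)
    expect_equal(colSums(tb), cols)
  }
})

test_that("Monte Carlo p-values are valid ranks", {
  map <- grid_geography(3)
  set.seed(13)
  ct <- case_table(matrix(rpois(9 * 4, 3) + 1, 9, 4), map = map)
  fit <- multinom_scan(ct, map = map, shapes = 1, angles = 1L,
                       R = 19, seed = 2)
  expect_true(all(fit$p_value >= 1 / 20 & fit$p_value <= 1))
  expect_length(fit$null_max_llr, 19)
})

test_that("ranked clusters are pairwise disjoint with non-increasing llr", {
  map <- grid_geography(4)
  set.seed(17)
  ct <- case_table(matrix(rpois(16 * 4, 3) + 1, 16, 4), map = map)
  fit <- multinom_scan(ct, map = map, R = 9, seed = 3)
  sets <- fit$windows$sets[fit$ranked]
  expect_false(anyDuplicated(unlist(sets)) > 0)
  expect_true(all(diff(fit$llr[fit$ranked]) <= 1e-12))
})

test_that("reports filter by size first, then overlap, then significance", {
  map <- grid_geography(8)
  sc <- design_scenario(map, "A", "1")
  ct <- simulate_dataset(sc, seed = 99)
  fit <- multinom_scan(ct, map = map, shapes = 1, angles = 1L,
                       R = 99, seed = 7)
  r50 <- report_at_mrcs(fit, 50)
  expect_true(all(r50$p_value <= fit$alpha))
  expect_true(all(r50$size_frac <= 0.5 + 1e-12))
  r5 <- report_at_mrcs(fit, 5)
  expect_true(all(r5$size_frac <= 0.05 + 1e-12))
  # a tiny m below every significant window yields an empty report
  r_tiny <- report_at_mrcs(fit, 0.01)
  expect_equal(nrow(r_tiny), 0)
  expect_error(report_at_mrcs(fit, 60), "\\(0, 50\\]")
})

test_that("a strongly contrasting planted cluster is recovered as the most likely cluster", {
  map <- grid_geography(8)
  truth <- plant_true_clusters(map, "circular", size_frac = 0.08)
  sc <- scan_scenario(map, truth, p0 = rep(0.25, 4),
                      p_list = list(c(0.85, 0.05, 0.05, 0.05)))
  hits <- 0
  for (s in 1:5) {
    ct <- simulate_dataset(sc, seed = 1000 + s)
    fit <- multinom_scan(ct, map = map, shapes = 1, angles = 1L,
                         R = 19, seed = s)
    top <- fit$windows$sets[[fit$ranked[1]]]
    if (identical(top, truth[[1]])) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
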