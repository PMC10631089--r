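test_that("the design table crosses models and hypotheses into 26 scenarios", {
  tab <- scenario_table()
  expect_equal(nrow(tab), 26)
  expect_equal(sum(tab$n_clusters == 1), 12)   # 3 models x 4 hypotheses
  expect_equal(sum(tab$n_clusters == 2), 14)   # 2 x (4 homogeneous + 3 hetero)
  hyp <- alt_hypotheses()
  expect_equal(hyp$p0, rep(0.25, 4))
  expect_equal(hyp$single[["1"]], c(0.05, 0.15, 0.35, 0.45))
  expect_equal(hyp$single[["2"]], c(0.05, 0.25, 0.25, 0.45))
  expect_equal(hyp$single[["3"]], c(0.10, 0.10, 0.40, 0.40))
  expect_equal(hyp$single[["4"]], c(0.15, 0.15, 0.15, 0.55))
  # heterogeneous settings pair hypothesis (1) with (2), (3), (4)
  for (h in c("5", "6", "7"))
    expect_equal(hyp$hetero[[h]][[1]], hyp$single[["1"]])
  expect_true(all(vapply(tab$p1, sum, numeric(1)) == 1))
})

test_that("planted clusters have the design sizes and are connected", {
  map <- grid_geography(8)
  circ <- plant_true_clusters(map, "circular", size_frac = 0.08)
  expect_length(circ[[1]], 5)           # round(0.08 * 64)
  ell <- plant_true_clusters(map, "elliptic", size_frac = 0.08)
  expect_length(ell[[1]], 5)
  set.seed(2)
  irr <- plant_true_clusters(map, "irregular", size_frac = 0.15)
  expect_length(irr[[1]], 10)           # round(0.15 * 64)
  nb <- mrcscan:::neighbor_list(map)
  for (cl in c(circ, ell, irr))
    expect_true(mrcscan:::is_connected(cl, nb))
  # two clusters: disjoint and both connected
  two <- plant_true_clusters(map, "circular", size_frac = 0.08, count = 2)
  expect_length(two, 2)
  expect_length(intersect(two[[1]], two[[2]]), 0)
  for (cl in two) expect_true(mrcscan:::is_connected(cl, nb))
  # an elliptic truth is elongated: wider x-extent than y-extent (angle 0)
  xy <- map$coords[ell[[1]], ]
  expect_gt(diff(range(xy[, 1])), diff(range(xy[, 2])))
})

test_that("simulated datasets hit the case total exactly and follow the mixture", {
  map <- grid_geography(8)
  sc <- design_scenario(map, "B", "1", n_cases = 1000)
  ct <- simulate_dataset(sc, seed = 7)
  expect_s3_class(ct, "case_table")
  expect_equal(ct$total, 1000)
  expect_equal(nrow(ct$counts), 64)

  # expected overall category mix: cluster share w with p1, rest with p0
  w <- length(sc$true_clusters[[1]]) / map$n
  p_mix <- w * sc$p_list[[1]] + (1 - w) * sc$p0
  for (s in 1:5) {
    ct_s <- simulate_dataset(sc, seed = 100 + s)
    se <- sqrt(p_mix * (1 - p_mix) / 1000)
    expect_true(all(abs(ct_s$col_totals / 1000 - p_mix) <= 3 * se))
  }

  # a null-probability "cluster" is exchangeable with a pure-null draw
  sc0 <- null_scenario(map)
  ct0 <- simulate_dataset(sc0, seed = 9)
  expect_equal(ct0$total, 1000)
})

test_that("detection accuracy follows the set arithmetic definitions", {
  expect_equal(performance_measures(1:5, 1:5, 69),
               c(sensitivity = 1, ppv = 1, misclassification = 0))
  expect_equal(performance_measures(6:10, 1:5, 69),
               c(sensitivity = 0, ppv = 0, misclassification = 10 / 69))
  expect_equal(performance_measures(4:9, 1:5, 69),
               c(sensitivity = 0.4, ppv = 1 / 3, misclassification = 7 / 69))
  # empty detection: zero sensitivity, PPV undefined
  pm <- performance_measures(integer(0), 1:5, 69)
  expect_equal(pm[["sensitivity"]], 0)
  expect_true(is.na(pm[["ppv"]]))
  # union denominator variant
  expect_equal(performance_measures(4:9, 1:5, 69, denominator = "union")[[3]],
               7 / 9)
  expect_error(performance_measures(1:3, integer(0), 69), "nonempty")
})

test_that("identical master seeds reproduce the study byte for byte", {
  map <- grid_geography(5)
  truth <- plant_true_clusters(map, "circular", size_frac = 0.12)
  sc <- scan_scenario(map, truth, p_list = list(c(0.05, 0.15, 0.35, 0.45)),
                      n_cases = 400)
  s1 <- run_simulation_study(sc, n_reps = 2, R = 49, seed = 77,
                             shapes = 1, angles = 1L)
  s2 <- run_simulation_study(sc, n_reps = 2, R = 49, seed = 77,
                             shapes = 1, angles = 1L)
  expect_identical(s1$per_rep, s2$per_rep)
  expect_identical(s1$table, s2$table)
  # and a different seed gives a different realisation of the data
  ct_a <- simulate_dataset(sc, seed = 1)
  ct_b <- simulate_dataset(sc, seed = 2)
  expect_false(identical(ct_a$counts, ct_b$counts))
})

test_that("the study summary has the frequency-table structure", {
  map <- grid_geography(5)
  truth <- plant_true_clusters(map, "circular", size_frac = 0.12)
  sc <- scan_scenario(map, truth, p_list = list(c(0.05, 0.15, 0.35, 0.45)),
                      n_cases = 400)
  s <- run_simulation_study(sc, n_reps = 3, R = 49, seed = 19,
                            shapes = 1, angles = 1L)
  tab <- s$table
  expect_setequal(unique(tab$measure),
                  c("freq", "sensitivity", "ppv", "misclassification"))
  # frequencies over the grid sum to the datasets with significant clusters
  for (meth in unique(tab$method)) {
    fr <- tab[tab$method == meth & tab$measure == "freq", ]
    expect_equal(sum(fr[paste0("m", s$grid)], na.rm = TRUE),
                 s$n_with_significant)
    expect_equal(fr$overall, s$n_with_significant)
  }
  sen <- tab[tab$measure == "sensitivity", c(paste0("m", s$grid), "overall")]
  expect_true(all(is.na(as.matrix(sen)) |
                  (as.matrix(sen) >= 0 & as.matrix(sen) <= 1)))
})
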