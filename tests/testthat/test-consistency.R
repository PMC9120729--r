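test_that("dice similarity follows set arithmetic", {
  a <- binary_edge_set(5, cbind(c(1, 1, 2), c(2, 3, 3)))
  b <- binary_edge_set(5, cbind(c(1, 1, 2), c(2, 3, 4)))
  expect_equal(dice_similarity(a, b), 2 * 2 / 6)
  expect_equal(dice_similarity(a, a), 1)
  expect_equal(dice_similarity(a, b), dice_similarity(b, a))
  disj <- binary_edge_set(5, cbind(4L, 5L))
  expect_equal(dice_similarity(a, disj), 0)
  empty <- binary_edge_set(5, matrix(integer(0), ncol = 2))
  expect_true(is.na(dice_similarity(empty, empty)))
  expect_equal(dice_similarity(a, empty), 0)
  expect_error(dice_similarity(a, binary_edge_set(4, cbind(1L, 2L))),
               "different node counts")
})

test_that("icc_oneway matches the aov mean-squares oracle", {
  # identical columns with item variance -> 1
  x <- cbind(c(1, 5, 9), c(1, 5, 9))
  expect_equal(icc_oneway(x), 1)
  # hand case from the one-way decomposition
  x <- cbind(c(1, 3, 5), c(2, 4, 6))
  expect_equal(icc_oneway(x), oracle_icc(x), tolerance = 1e-12)
  # random inputs, including k > 2
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(3:12, 1); k <- sample(2:4, 1)
    x <- matrix(rnorm(n * k, sd = sample(c(0.5, 5), 1)), n, k) +
      rnorm(n)  # item effects
    expect_equal(icc_oneway(x), oracle_icc(x), tolerance = 1e-10)
  }
  # degenerate variance -> NA
  expect_true(is.na(icc_oneway(matrix(3, 4, 2))))
})

test_that("icc_oneway is location and positive-scale invariant", {
  set.seed(7)
  for (rep in 1:20) {
    x <- matrix(rnorm(16), 8, 2) + rnorm(8)
    base <- icc_oneway(x)
    expect_equal(icc_oneway(x + 100), base, tolerance = 1e-9)
    expect_equal(icc_oneway(x * 3.7), base, tolerance = 1e-9)
  }
})

test_that("white-noise columns give ICC near zero", {
  set.seed(123)
  x <- matrix(rnorm(2 * 5000), ncol = 2)
  expect_lt(abs(icc_oneway(x)), 0.05)
})

test_that("edge_weight_icc works over the common kept edges", {
  wc <- random_connectome(8, density = 0.6, seed = 9)
  expect_equal(edge_weight_icc(wc, wc), 1)
  # constructed: common edges with swapped weights -> matches oracle
  n <- 5
  nos_a <- sym_from_edges(n, cbind(c(1, 2, 3, 1), c(2, 3, 4, 5)),
                          c(10, 20, 30, 7))
  nos_b <- sym_from_edges(n, cbind(c(1, 2, 3, 2), c(2, 3, 4, 5)),
                          c(30, 20, 10, 9))
  a <- weighted_connectome(nos_a); b <- weighted_connectome(nos_b)
  got <- edge_weight_icc(a, b)
  expect_equal(got, oracle_icc(cbind(c(10, 20, 30), c(30, 20, 10))),
               tolerance = 1e-12)
  # empty intersection -> NA
  c1 <- weighted_connectome(sym_from_edges(5, cbind(1, 2), 5))
  c2 <- weighted_connectome(sym_from_edges(5, cbind(3, 4), 5))
  expect_true(is.na(edge_weight_icc(c1, c2)))
})

test_that("hub_score_icc compares aligned node metric vectors", {
  d1 <- node_degree(binary_edge_set(4, cbind(c(1, 1, 1), c(2, 3, 4))))
  expect_equal(hub_score_icc(d1, d1), 1)
  v1 <- netsweep:::new_node_metric("degree", c(1, 2, 3))
  v2 <- netsweep:::new_node_metric("degree", c(3, 2, 1))
  expect_equal(hub_score_icc(v1, v2),
               oracle_icc(cbind(c(1, 2, 3), c(3, 2, 1))),
               tolerance = 1e-12)
  v3 <- netsweep:::new_node_metric("betweenness", c(1, 2, 3))
  expect_error(hub_score_icc(v1, v3), "metrics differ")
  # shuffling one session's nodes lowers the ICC on structured graphs
  set.seed(5)
  wc <- random_connectome(12, density = 0.3, seed = 61)
  dv <- node_degree(edge_set(wc))
  worse <- 0
  for (rep in 1:20) {
    perm <- netsweep:::new_node_metric("degree", sample(dv$values))
    if (hub_score_icc(dv, perm) < hub_score_icc(dv, dv)) worse <- worse + 1
  }
  expect_gte(worse, 19)
})

test_that("consistency_sweep on the identity cohort is 1 everywhere", {
  gen <- generate_cohort(identity_generator_config(n_nodes = 20,
                                                   n_subjects = 3))
  for (method in c("fixed_density", "absolute")) {
    levels <- if (method == "fixed_density") c(0.1, 0.15, 0.2) else
      c(1, 3, 5)
    cs <- consistency_sweep(gen$cohort, method, levels = levels)
    thr <- cs$rows[!is.na(cs$level), ]
    expect_true(all(thr$dice == 1))
    expect_true(all(thr$icc_edge_weight == 1, na.rm = TRUE))
    expect_true(all(thr$icc_degree == 1, na.rm = TRUE))
    expect_true(all(thr$icc_betweenness == 1, na.rm = TRUE))
  }
})

test_that("consistency_sweep summary has the grid and argmax structure", {
  gen <- small_cohort(n_subjects = 4, n_nodes = 24, seed = 17)
  cs <- consistency_sweep(gen$cohort, "fixed_density",
                          levels = seq(0.1, 0.3, 0.05),
                          statistics = c("dice", "icc_edge_weight"))
  expect_setequal(unique(cs$summary$statistic),
                  c("dice", "icc_edge_weight"))
  dice_sum <- cs$summary[cs$summary$statistic == "dice", ]
  expect_equal(sum(!is.na(dice_sum$level)), 5L)  # grid + unthresholded row
  expect_true(all(dice_sum$n == 4))
  expect_true(cs$argmax[["dice"]] %in% seq(0.1, 0.3, 0.05))
  # full default grids have 39 / 40 levels
  expect_length(default_grid("fixed_density"), 39L)
  expect_length(default_grid("absolute"), 40L)
})

test_that("compare_to_unthresholded handles identity, shift and null", {
  x <- stats::setNames(rep(0.7, 10), paste0("s", 1:10))
  expect_equal(compare_to_unthresholded(x, x), 1)
  # constant positive shift with small jitter across 86 subjects
  set.seed(11)
  u <- stats::setNames(runif(86, 0.6, 0.8), paste0("s", 1:86))
  shifted <- u + 0.06 + rnorm(86, sd = 0.01)
  expect_lt(compare_to_unthresholded(shifted, u), 1e-3)
  # antisymmetric differences -> non-significant
  d <- rep(c(-0.05, 0.05), 20)
  expect_gt(compare_to_unthresholded(u[1:40] + d, u[1:40]), 0.5)
  # too few pairs -> NA
  expect_true(is.na(compare_to_unthresholded(c(a = 1, b = 2),
                                             c(a = 1, b = 2))))
  # wilcoxon family is available
  expect_lt(compare_to_unthresholded(shifted, u, test = "wilcoxon"), 1e-3)
})
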