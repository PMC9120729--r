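test_that("template respects density, connectivity and determinism", {
  cfg <- generator_config(n_nodes = 40, n_subjects = 4, seed = 5,
                          true_density = 0.2)
  tpl <- generate_template(cfg)
  expect_equal(nrow(tpl$true_edges$edges), round(0.2 * 40 * 39 / 2))
  g <- netsweep:::es_to_igraph(tpl$true_edges)
  expect_true(igraph::is_connected(g))
  expect_true(all(tpl$nos >= 1))
  expect_true(all(tpl$fa > 0 & tpl$fa < 1))
  expect_true(all(tpl$md > 0))
  # full density -> complete graph
  cfg1 <- generator_config(n_nodes = 10, n_subjects = 2, seed = 5,
                           true_density = 1)
  expect_equal(nrow(generate_template(cfg1)$true_edges$edges), 45L)
  # minimal density stays connected
  cfg2 <- generator_config(n_nodes = 30, n_subjects = 2, seed = 5,
                           true_density = 2 / 30)
  tpl2 <- generate_template(cfg2)
  expect_true(igraph::is_connected(netsweep:::es_to_igraph(tpl2$true_edges)))
  # same seed -> identical template
  expect_identical(generate_template(cfg), tpl)
})

test_that("noise-free sessions reproduce the template exactly", {
  cfg <- identity_generator_config(n_nodes = 25, n_subjects = 2)
  tpl <- generate_template(cfg)
  s <- generate_session(tpl, cfg, 1, "baseline", "low")
  expect_equal(edge_set(s$connectome)$edges, tpl$true_edges$edges)
  expect_equal(s$connectome$weights$NOS[tpl$true_edges$edges], tpl$nos)
  expect_equal(nrow(s$fp_edges), 0L)
  expect_equal(nrow(s$dropped_edges), 0L)
  # follow-up identical too (no decline configured)
  f <- generate_session(tpl, cfg, 1, "followup", "low")
  expect_equal(f$connectome$weights, s$connectome$weights)
})

test_that("false-positive count matches its binomial expectation", {
  cfg <- generator_config(seed = 31)   # N = 90, density .15, fp .05
  tpl <- generate_template(cfg)
  n_absent <- 90 * 89 / 2 - nrow(tpl$true_edges$edges)
  counts <- vapply(1:20, function(k)
    nrow(generate_session(tpl, cfg, k, "baseline", "low")$fp_edges), 1L)
  expected <- 0.05 * n_absent
  tol <- 3 * sqrt(0.05 * 0.95 * n_absent / 20)
  expect_lt(abs(mean(counts) - expected), tol)
})

test_that("false negatives hit weak edges hardest", {
  cfg <- generator_config(seed = 13, n_subjects = 4)
  tpl <- generate_template(cfg)
  dropped_w <- unlist(lapply(1:4, function(k) {
    s <- generate_session(tpl, cfg, k, "baseline", "low")
    ids_t <- (tpl$true_edges$edges[, 1] - 1) * 90 + tpl$true_edges$edges[, 2]
    ids_d <- (s$dropped_edges[, 1] - 1) * 90 + s$dropped_edges[, 2]
    tpl$nos[ids_t %in% ids_d]
  }))
  expect_gt(length(dropped_w), 0)
  expect_lt(median(dropped_w), median(tpl$nos))
})

test_that("false-positive weights sit below the bulk of true weights", {
  cfg <- generator_config(seed = 77)
  tpl <- generate_template(cfg)
  s <- generate_session(tpl, cfg, 1, "baseline", "low")
  fp_w <- s$connectome$weights$NOS[s$fp_edges]
  expect_true(all(fp_w >= 1 & fp_w <= 5))
  expect_gt(stats::quantile(tpl$nos, 0.75), max(fp_w))
  # overlapping configuration warns
  expect_warning(generator_config(nos_meanlog = 0.5, nos_sdlog = 0.5),
                 "overlap")
})

test_that("cohorts are reproducible and carry ground truth", {
  cfg <- generator_config(n_nodes = 30, n_subjects = 6, seed = 19)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort$subjects[[3]]$baseline$weights,
                   g2$cohort$subjects[[3]]$baseline$weights)
  expect_identical(g1$ground_truth, g2$ground_truth)
  gt <- g1$ground_truth
  expect_equal(length(gt$sessions), 6L)
  expect_equal(gt$groups, rep(c("low", "high"), 3))
  expect_length(gt$subject_params, 6L)
  expect_named(gt$subject_params[[1]],
               c("log_scale", "fa_offset", "md_offset"))
  # WMH volumes separate the groups (upper-tail sampling for high)
  wmh <- vapply(g1$cohort$subjects, function(s) s$wmh_volume, 1.0)
  expect_equal(median_split(wmh), gt$groups)
  # subject streams are independent of cohort size: subject 2 is the same
  # in a larger cohort with the same seed
  cfg_big <- generator_config(n_nodes = 30, n_subjects = 8, seed = 19)
  g3 <- generate_cohort(cfg_big)
  expect_identical(g3$cohort$subjects[[2]]$baseline$weights,
                   g1$cohort$subjects[[2]]$baseline$weights)
})

test_that("dice between sessions improves after thresholding at true density", {
  cfg <- generator_config(n_nodes = 60, n_subjects = 1, seed = 23,
                          true_density = 0.15)
  tpl <- generate_template(cfg)
  a <- generate_session(tpl, cfg, 1, "baseline", "low")$connectome
  b <- generate_session(tpl, cfg, 1, "followup", "low")$connectome
  raw <- dice_similarity(edge_set(a), edge_set(b))
  expect_lt(raw, 1)
  ta <- apply_fixed_density(a, 0.15)
  tb <- apply_fixed_density(b, 0.15)
  expect_gt(dice_similarity(ta$kept, tb$kept), raw)
})

test_that("thresholding at true density recovers the backbone as fp weights separate", {
  prf <- function(meanlog) {
    cfg <- suppressWarnings(
      generator_config(n_nodes = 60, n_subjects = 1, seed = 3,
                       true_density = 0.15, nos_meanlog = meanlog,
                       fn_intercept = -50))
    tpl <- generate_template(cfg)
    s <- generate_session(tpl, cfg, 1, "baseline", "low")$connectome
    kept <- apply_fixed_density(s, 0.15)$kept
    ids_true <- (tpl$true_edges$edges[, 1] - 1) * 60 +
      tpl$true_edges$edges[, 2]
    ids_kept <- (kept$edges[, 1] - 1) * 60 + kept$edges[, 2]
    tp <- sum(ids_kept %in% ids_true)
    c(precision = tp / length(ids_kept), recall = tp / length(ids_true))
  }
  weak <- prf(2)     # weights overlap the 1-5 fp band more
  strong <- prf(5)   # well separated
  expect_gte(strong["precision"], weak["precision"])
  expect_gt(strong["precision"], 0.95)
  expect_gt(strong["recall"], 0.95)
})
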