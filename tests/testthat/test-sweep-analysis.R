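test_that("longitudinal z-scores standardise by baseline mean/SD", {
  b <- cbind(l1 = c(1, 2, 3), l2 = c(10, 20, 30))
  f <- b
  z <- longitudinal_zscores(b, f)
  # sample-SD convention: (1,2,3) -> (-1, 0, 1)
  expect_equal(unname(z$z_baseline[, 1]), c(-1, 0, 1))
  expect_equal(colMeans(z$z_baseline), c(l1 = 0, l2 = 0), tolerance = 1e-10)
  expect_equal(apply(z$z_baseline, 2, sd), c(l1 = 1, l2 = 1),
               tolerance = 1e-10)
  # follow-up identical to baseline -> change == 0
  expect_true(all(z$change == 0))
  # adding a constant to follow-up shifts all change scores equally (in
  # baseline-SD units)
  z2 <- longitudinal_zscores(b, f + 0.5)
  expect_equal(unname(z2$change[, 1]), rep(-0.5 / 1, 3), tolerance = 1e-10)
  expect_equal(unname(z2$change[, 2]), rep(-0.5 / 10, 3), tolerance = 1e-10)
  # degenerate baseline level flagged
  z3 <- longitudinal_zscores(cbind(c(1, 1, 1), b[, 1]), f)
  expect_equal(z3$degenerate_levels, 1L)
  expect_true(all(is.na(z3$z_baseline[, 1])))
})

test_that("cross-threshold correlation matrix is symmetric with unit diag", {
  set.seed(3)
  z <- matrix(rnorm(50 * 4), 50, 4)
  colnames(z) <- paste0("l", 1:4)
  z[, 2] <- z[, 1]              # exact copy -> r = 1
  z[, 3] <- -z[, 1]             # negation -> r = -1
  ct <- cross_threshold_correlation(z)
  expect_equal(ct$r_matrix, t(ct$r_matrix))
  expect_equal(unname(diag(ct$r_matrix)), rep(1, 4))
  expect_equal(ct$r_matrix["l1", "l2"], 1)
  expect_equal(ct$r_matrix["l1", "l3"], -1)
  expect_true(all(abs(ct$r_matrix) <= 1 + 1e-12))
  # independent columns, many subjects -> r near 0
  set.seed(4)
  big <- matrix(rnorm(500 * 2), 500, 2)
  r <- cross_threshold_correlation(big)$r_matrix[1, 2]
  expect_lt(abs(r), 0.1)
  # degenerate column -> NA cells
  z[, 4] <- 5
  ct2 <- cross_threshold_correlation(z)
  expect_true(all(is.na(ct2$r_matrix[, 4])))
})

test_that("baseline/follow-up correlation shows analytic attenuation", {
  b <- matrix(rnorm(4000), 2000, 2, dimnames = list(NULL, c("a", "b")))
  set.seed(9)
  b[] <- rnorm(4000)
  # follow-up = baseline -> r = 1
  z <- longitudinal_zscores(b, b)
  expect_equal(unname(baseline_followup_correlation(z)), c(1, 1))
  # equal-variance independent noise -> r ~ 1/sqrt(2)
  f <- b + matrix(rnorm(4000), 2000, 2)
  z2 <- longitudinal_zscores(b, f)
  expect_equal(unname(baseline_followup_correlation(z2)),
               rep(1 / sqrt(2), 2), tolerance = 0.05)
  # independent follow-up -> r ~ 0
  z3 <- longitudinal_zscores(b, matrix(rnorm(4000), 2000, 2))
  expect_lt(max(abs(baseline_followup_correlation(z3))), 0.1)
})

test_that("median split sends the median element to the low group", {
  expect_equal(median_split(c(1, 2, 3, 4)), c("low", "low", "high", "high"))
  expect_equal(median_split(c(1, 2, 3)), c("low", "low", "high"))
  got <- median_split(c(5, NA, 1, 9))
  expect_true(is.na(got[2]))
  expect_equal(got[-2], c("low", "low", "high"))
  expect_error(median_split(c(2, 2, 2)), "undefined")
  expect_error(median_split(c(NA, 3)), "non-missing")
})

test_that("mixed_anova matches the balanced split-plot oracle", {
  set.seed(21)
  for (rep in 1:25) {
    m <- sample(c(4, 6, 10), 1)
    g <- rep(c("low", "high"), each = m)
    y <- matrix(rnorm(2 * m * 2), ncol = 2) +
      rnorm(2 * m) +                                    # subject effects
      outer(as.numeric(g == "high"), c(0, 0.6)) +       # interaction-ish
      outer(rep(1, 2 * m), c(0, sample(c(0, 0.8), 1)))  # time shift
    res <- mixed_anova(y[, 1], y[, 2], g)
    oracle <- oracle_mixed_anova_f(y, g)
    expect_equal(res$F[res$effect == "time"], unname(oracle["time"]),
                 tolerance = 1e-8)
    expect_equal(res$F[res$effect == "group"], unname(oracle["group"]),
                 tolerance = 1e-8)
    expect_equal(res$F[res$effect == "interaction"],
                 unname(oracle["interaction"]), tolerance = 1e-8)
    expect_equal(res$df1, rep(1L, 3))
    expect_equal(res$df2, rep(2L * m - 2L, 3))
  }
})

test_that("mixed_anova isolates constructed effects", {
  set.seed(8)
  m <- 20
  g <- rep(c("low", "high"), each = m)
  subj <- rnorm(2 * m)
  # pure additive time effect, no group difference
  b <- subj + rnorm(2 * m, sd = 0.3)
  f <- subj - 0.5 + rnorm(2 * m, sd = 0.3)
  res <- mixed_anova(b, f, g)
  expect_gt(res$F[res$effect == "time"], critical_f(2 * m - 2))
  expect_lt(res$F[res$effect == "group"], critical_f(2 * m - 2))
  # identity data with identical group distributions -> all F = 0
  subj <- rep(rnorm(m), 2)
  res0 <- mixed_anova(subj, subj, g)
  expect_equal(res0$F, rep(0, 3))
  expect_equal(res0$cohens_d, rep(0, 3))
  # groups too small -> error; missing group labels are dropped first
  expect_error(mixed_anova(1:5, 2:6, c("low", "low", "high", "high",
                                       "high")), ">= 3")
})

test_that("mixed_anova type-I error is calibrated on Gaussian nulls", {
  set.seed(101)
  n_rep <- 400
  rej <- matrix(FALSE, n_rep, 3)
  for (r in seq_len(n_rep)) {
    subj <- rnorm(30)
    b <- subj + rnorm(30, sd = 0.5)
    f <- subj + rnorm(30, sd = 0.5)
    res <- mixed_anova(b, f, rep(c("low", "high"), each = 15))
    rej[r, ] <- res$p < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates > 0.02 & rates < 0.09))
})

test_that("group-effect rejection rate grows with injected effect size", {
  set.seed(55)
  power_at <- function(d) {
    hits <- 0
    for (r in 1:60) {
      subj <- rnorm(40) + d * rep(c(0, -1), each = 20)
      b <- subj + rnorm(40, sd = 0.3)
      f <- subj + rnorm(40, sd = 0.3)
      res <- mixed_anova(b, f, rep(c("low", "high"), each = 20))
      if (res$p[res$effect == "group"] < 0.05) hits <- hits + 1
    }
    hits / 60
  }
  p <- vapply(c(0, 0.8, 2), power_at, 1.0)
  expect_true(all(diff(p) >= 0))
  expect_lt(p[1], 0.2)
  expect_gt(p[3], 0.9)
})

test_that("sensitivity_sweep runs per level and reports exclusions", {
  gen <- small_cohort(n_subjects = 8, n_nodes = 24, seed = 31)
  levels <- c(0.15, 0.2, 0.25)
  sw <- sensitivity_sweep(gen$cohort, "mean_strength_FA", "fixed_density",
                          levels = levels)
  expect_equal(sort(unique(sw$anova$level)), levels)
  expect_equal(nrow(sw$anova), 3L * 3L)
  expect_true(all(c("F", "p", "cohens_d", "critical_F") %in%
                    names(sw$anova)))
  expect_equal(dim(sw$values_baseline), c(8L, 3L))
  # deterministic given the same input
  sw2 <- sensitivity_sweep(gen$cohort, "mean_strength_FA",
                           "fixed_density", levels = levels)
  expect_identical(sw$anova, sw2$anova)
  # identity cohort: time and interaction F exactly 0
  id <- generate_cohort(identity_generator_config(n_nodes = 24,
                                                  n_subjects = 8))
  swi <- sensitivity_sweep(id$cohort, "mean_strength_FA", "fixed_density",
                           levels = levels)
  expect_true(all(swi$anova$F[swi$anova$effect == "time"] == 0))
})

test_that("fast fixed-density strength sweep equals the rethreshold route", {
  wc <- random_connectome(20, density = 0.6, seed = 71, channels = TRUE)
  levels <- c(0.11, 0.2, 0.33)
  fast <- netsweep:::strength_sweep_fixed_density(wc, levels, "FA")
  slow <- vapply(levels, function(d) {
    st <- node_strength(apply_fixed_density(wc, d), "FA")
    ok <- setdiff(seq_along(st$values), st$undefined_nodes)
    mean(st$values[ok])
  }, 1.0)
  expect_equal(fast, slow, tolerance = 1e-12)
})
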