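# Sensitivity-to-disease-effects analysis: longitudinal z-scoring of
# subject-level metrics, cross-threshold Pearson correlation matrices,
# WMH median-split grouping, and a 2x2 mixed ANOVA (time within, group
# between) computed from explicit Type III sums of squares.

#' Longitudinal z-scores of a subject x level metric matrix
#'
#' Baseline values are standardised per threshold level across subjects;
#' follow-up values are standardised with the *baseline* mean and SD of the
#' same level, so that follow-up z-scores express change relative to the
#' baseline distribution. The change score is `baseline - followup`
#' (positive = decline). The sample (n-1) SD is used.
#'
#' @param values_baseline,values_followup numeric subjects x levels
#'   matrices (column names carry the levels)
#' @return object of class `longitudinal_zscores`: list with `z_baseline`,
#'   `z_followup`, `change`, and `degenerate_levels` (columns with zero
#'   baseline SD, whose z-scores are `NA`)
#' @export
longitudinal_zscores <- function(values_baseline, values_followup) {
  b <- as.matrix(values_baseline)
  f <- as.matrix(values_followup)
  if (!all(dim(b) == dim(f)))
    stop("baseline and follow-up matrices must have identical shape")
  if (nrow(b) < 3L) stop("need at least 3 subjects")
  mu <- colMeans(b)
  sdev <- apply(b, 2L, stats::sd)
  degenerate <- which(sdev == 0 | is.na(sdev))
  sdev[degenerate] <- NA_real_
  zb <- sweep(sweep(b, 2L, mu), 2L, sdev, "/")
  zf <- sweep(sweep(f, 2L, mu), 2L, sdev, "/")
  structure(list(z_baseline = zb, z_followup = zf, change = zb - zf,
                 degenerate_levels = degenerate),
            class = "longitudinal_zscores")
}

#' Cross-threshold correlation matrix
#'
#' Pearson correlations, over subjects, between metric values obtained at
#' every pair of threshold levels. High off-diagonal correlations mean the
#' interindividual variation (each subject's position relative to the group)
#' is preserved when the threshold changes.
#'
#' @param z numeric subjects x levels matrix (raw or z-scored values;
#'   Pearson correlation is invariant to the standardisation)
#' @return object of class `cross_threshold_correlation`: list with
#'   `levels` and the symmetric unit-diagonal `r_matrix` (cells with
#'   degenerate variance are `NA`)
#' @export
cross_threshold_correlation <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 3L) stop("need at least 3 subjects")
  sds <- apply(z, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(z))
  r[sds == 0 | is.na(sds), ] <- NA_real_
  r[, sds == 0 | is.na(sds)] <- NA_real_
  diag(r) <- ifelse(is.na(sds) | sds == 0, NA_real_, 1)
  structure(list(levels = colnames(z), r_matrix = r),
            class = "cross_threshold_correlation")
}

#' Per-level correlation between baseline and follow-up
#'
#' Pearson r, across subjects, between baseline and follow-up metric
#' values within each threshold level — high values mean subjects keep
#' their relative position in the group over time.
#'
#' @param z a `longitudinal_zscores` object
#' @return named numeric vector of per-level correlations
#' @export
baseline_followup_correlation <- function(z) {
  stopifnot(inherits(z, "longitudinal_zscores"))
  n_lev <- ncol(z$z_baseline)
  out <- rep(NA_real_, n_lev)
  for (t in seq_len(n_lev)) {
    b <- z$z_baseline[, t]; f <- z$z_followup[, t]
    if (anyNA(b) || anyNA(f) || stats::sd(b) == 0 || stats::sd(f) == 0)
      next
    out[t] <- stats::cor(b, f)
  }
  names(out) <- colnames(z$z_baseline)
  out
}

#' Median split of WMH volumes
#'
#' Subjects with volume above the median go to the `"high"` group; at or
#' below the median to `"low"` (so with odd n the median element is
#' assigned low). Subjects with missing volume get `NA` and are excluded
#' from the ANOVA stage.
#'
#' @param wmh_volumes per-subject WMH volumes (ml), `NA` allowed
#' @return character vector of `"low"`/`"high"`/`NA` labels
#' @export
median_split <- function(wmh_volumes) {
  ok <- !is.na(wmh_volumes)
  if (sum(ok) < 2L) stop("need at least 2 non-missing volumes")
  v <- wmh_volumes[ok]
  if (max(v) == min(v)) stop("all volumes equal; median split undefined")
  med <- stats::median(v)
  out <- rep(NA_character_, length(wmh_volumes))
  out[ok] <- ifelse(v > med, "high", "low")
  out
}

#' Two-by-two mixed ANOVA (time within, group between)
#'
#' F statistics for the effect of time (baseline vs follow-up,
#' within-subject), group (low vs high, between-subject) and their
#' interaction, each on `(1, n - 2)` degrees of freedom, computed from
#' explicit Type III sums of squares of the split-plot design so that
#' unbalanced groups are handled without relying on any one stats
#' package's defaults. When an effect's sum of squares is exactly zero the
#' F is reported as 0 even if the error term is also degenerate (the
#' identity-cohort case).
#'
#' Cohen's d conventions (recorded here because the magnitude depends on
#' them): time = mean paired difference / pooled SD of the two sessions;
#' group = difference of group means / pooled between-subject SD of
#' subject means; interaction = difference of the two groups' mean changes
#' / pooled SD of change scores.
#'
#' @param baseline,followup per-subject metric values
#' @param group per-subject `"low"`/`"high"` labels; `NA` rows are dropped
#' @return data frame, one row per effect, with `effect`, `F`, `df1`,
#'   `df2`, `p`, `cohens_d`
#' @export
mixed_anova <- function(baseline, followup, group) {
  ok <- !is.na(baseline) & !is.na(followup) & !is.na(group)
  b <- baseline[ok]; f <- followup[ok]; g <- as.character(group[ok])
  if (!all(g %in% c("low", "high"))) stop("group labels must be low/high")
  n1 <- sum(g == "low"); n2 <- sum(g == "high")
  if (n1 < 3L || n2 < 3L)
    stop(sprintf("each group needs >= 3 subjects (low = %d, high = %d)",
                 n1, n2))
  n <- n1 + n2
  d <- b - f                      # change score, positive = decline
  u <- (b + f) / 2                # subject mean
  d1 <- mean(d[g == "low"]);  d2 <- mean(d[g == "high"])
  u1 <- mean(u[g == "low"]);  u2 <- mean(u[g == "high"])
  # pooled residual variances (within-group)
  ss_d <- sum((d[g == "low"] - d1)^2) + sum((d[g == "high"] - d2)^2)
  ss_u <- sum((u[g == "low"] - u1)^2) + sum((u[g == "high"] - u2)^2)
  var_d <- ss_d / (n - 2)         # within-subject (session x subject) error
  var_u <- ss_u / (n - 2)         # between-subject error (subject means)
  w <- 1 / n1 + 1 / n2
  f_stat <- function(num, err) {
    if (num == 0) return(0)
    if (err == 0) return(Inf)
    num / err
  }
  # Type III contrasts for the 2x2 mixed design
  f_time  <- f_stat(((d1 + d2) / 2)^2, var_d * w / 4)
  f_group <- f_stat((u1 - u2)^2,       var_u * w)
  f_inter <- f_stat((d1 - d2)^2,       var_d * w)
  pooled_session_sd <- sqrt((stats::var(b) + stats::var(f)) / 2)
  d_time <- if (pooled_session_sd == 0) 0 else mean(d) / pooled_session_sd
  sd_u <- sqrt(ss_u / (n - 2))
  d_group <- if (sd_u == 0) 0 else (u1 - u2) / sd_u
  sd_d <- sqrt(ss_d / (n - 2))
  d_inter <- if (sd_d == 0) 0 else (d1 - d2) / sd_d
  eff <- data.frame(
    effect = c("time", "group", "interaction"),
    F = c(f_time, f_group, f_inter),
    df1 = 1L, df2 = n - 2L,
    p = stats::pf(c(f_time, f_group, f_inter), 1, n - 2,
                  lower.tail = FALSE),
    cohens_d = c(d_time, d_group, d_inter),
    stringsAsFactors = FALSE)
  attr(eff, "n") <- c(low = n1, high = n2)
  attr(eff, "n_excluded") <- sum(!ok)
  eff
}

#' Critical F at a significance level
#' @param df2 denominator degrees of freedom
#' @param alpha significance level (default 0.05)
#' @return critical F value on `(1, df2)` degrees of freedom
#' @export
critical_f <- function(df2, alpha = 0.05) {
  stats::qf(1 - alpha, 1, df2)
}

#' Per-level mixed-ANOVA sensitivity sweep
#'
#' Computes the subject-level metric at every threshold level for both
#' sessions, stratifies subjects by a median split of WMH volume (unless
#' explicit groups are carried by the cohort), and runs [mixed_anova()]
#' per level. Subjects with missing WMH volume are excluded from this
#' stage only, with counts reported.
#'
#' @param x a `cohort`
#' @param metric `"global_efficiency"`, `"mean_strength_FA"` or
#'   `"mean_strength_MD"`
#' @param method thresholding method (fixed density recommended: it keeps
#'   network size constant across levels)
#' @param levels threshold grid
#' @param use_recorded_groups take group labels from the cohort when all
#'   present (default `FALSE`: recompute the median split from WMH volume)
#' @param efficiency_convention passed to [global_efficiency()]
#' @return list with `anova` (long per-level effect table including the
#'   critical F at alpha = .05), `values_baseline`/`values_followup`
#'   (subject x level matrices), `groups`, `n_excluded`
#' @export
sensitivity_sweep <- function(x, metric = c("global_efficiency",
                                            "mean_strength_FA",
                                            "mean_strength_MD"),
                              method = c("fixed_density", "absolute"),
                              levels = NULL,
                              use_recorded_groups = FALSE,
                              efficiency_convention = "mean_inverse") {
  metric <- match.arg(metric)
  method <- match.arg(method)
  if (is.null(levels)) {
    n0 <- if (length(x$subjects)) n_nodes(x$subjects[[1L]]$baseline) else NULL
    levels <- default_grid(method, n0)
  }
  levels <- sort(levels)
  vals <- metric_value_matrices(x, metric, method, levels,
                                efficiency_convention)
  groups <- if (use_recorded_groups) {
    vapply(x$subjects, function(s) as.character(s$group), "")
  } else {
    median_split(vapply(x$subjects, function(s) s$wmh_volume, 1.0))
  }
  rows <- list()
  for (li in seq_along(levels)) {
    a <- mixed_anova(vals$baseline[, li], vals$followup[, li], groups)
    a$level <- levels[li]
    a$critical_F <- critical_f(a$df2[1L])
    rows[[li]] <- a
  }
  anova_tab <- do.call(rbind, rows)
  list(anova = anova_tab, values_baseline = vals$baseline,
       values_followup = vals$followup, groups = groups,
       n_excluded = sum(is.na(groups)), metric = metric, method = method,
       levels = levels)
}

# Subject x level metric matrices for both sessions. Fixed-density strength
# metrics use an incremental prefix computation (edges enter in threshold
# order) instead of re-thresholding at every level.
metric_value_matrices <- function(x, metric, method, levels,
                                  efficiency_convention = "mean_inverse") {
  ns <- length(x$subjects)
  out_b <- matrix(NA_real_, ns, length(levels))
  out_f <- matrix(NA_real_, ns, length(levels))
  colnames(out_b) <- colnames(out_f) <- format(levels, trim = TRUE)
  rownames(out_b) <- rownames(out_f) <-
    vapply(x$subjects, function(s) s$subject_id, "")
  channel <- sub("mean_strength_", "", metric)
  for (si in seq_len(ns)) {
    s <- x$subjects[[si]]
    for (session in c("baseline", "followup")) {
      conn <- s[[session]]
      v <- if (metric != "global_efficiency" && method == "fixed_density") {
        strength_sweep_fixed_density(conn, levels, channel)
      } else {
        vapply(run_sweep(conn, method, levels), function(tc) {
          if (metric == "global_efficiency")
            global_efficiency(tc$kept,
                              convention = efficiency_convention)$value
          else {
            st <- node_strength(tc, channel)
            okn <- setdiff(seq_along(st$values), st$undefined_nodes)
            if (length(okn)) mean(st$values[okn]) else NA_real_
          }
        }, 1.0)
      }
      if (session == "baseline") out_b[si, ] <- v else out_f[si, ] <- v
    }
  }
  list(baseline = out_b, followup = out_f)
}

# Mean FA/MD node strength across a fixed-density grid in one pass:
# order edges as [MST, then non-MST strongest-first]; the kept set at a
# level is a prefix of that order, so per-node sums accumulate.
strength_sweep_fixed_density <- function(conn, levels, channel) {
  n <- n_nodes(conn)
  re <- ranked_edges(conn)
  mask <- mst_mask(conn, re)
  ord <- c(which(mask), which(!mask))
  i <- re$i[ord]; j <- re$j[ord]
  w <- conn$weights[[channel]][cbind(i, j)]
  n_possible <- n * (n - 1) / 2
  targets <- pmax(as.integer(round_half_up(levels * n_possible)), n - 1L)
  targets <- pmin(targets, length(ord))   # shortfall: keep all edges
  vapply(targets, function(m) {
    sel <- seq_len(m)
    sums <- numeric(n); cnts <- integer(n)
    agg <- rowsum(c(w[sel], w[sel]), c(i[sel], j[sel]))
    sums[as.integer(rownames(agg))] <- agg[, 1]
    cnts <- tabulate(c(i[sel], j[sel]), nbins = n)
    mean(sums[cnts > 0L] / cnts[cnts > 0L])
  }, 1.0)
}
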