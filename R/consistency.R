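# Scan-rescan consistency statistics: dice similarity of edge sets, one-way
# intraclass correlation of edge weights over common edges and of hub
# scores (degree, betweenness centrality), swept over threshold grids, plus
# the paired comparison of a threshold level against unthresholded.

#' Dice similarity of two edge sets
#'
#' `2 |a intersect b| / (|a| + |b|)`: 0 means no overlap, 1 complete
#' overlap of the edges detected at scan and rescan. When both sets are
#' empty the coefficient is undefined and reported as `NA` (not 0 or 1).
#'
#' @param a,b `binary_edge_set`s over the same node count
#' @return dice coefficient in `[0, 1]`, or `NA`
#' @export
dice_similarity <- function(a, b) {
  if (a$n_nodes != b$n_nodes) stop("edge sets have different node counts")
  na <- nrow(a$edges); nb <- nrow(b$edges)
  if (na + nb == 0L) return(NA_real_)
  common <- sum(edge_ids(a) %in% edge_ids(b))
  2 * common / (na + nb)
}

#' One-way random-effects intraclass correlation
#'
#' ICC from the one-way ANOVA decomposition over items:
#' `(MSb - MSw) / (MSb + (k - 1) MSw)` with `MSb` the between-item and
#' `MSw` the within-item mean square, and `k` the number of repeated
#' measurements (sessions). This is the single-measurement one-way form;
#' negative values are reported as computed, not clamped.
#'
#' @param x numeric matrix, items (edges or nodes) in rows, the `k >= 2`
#'   repeated measurements in columns; no missing cells.
#' @return the ICC, or `NA` when the total variance is zero
#' @export
icc_oneway <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L) stop("need at least 2 items")
  if (k < 2L) stop("need at least 2 repeated measurements")
  if (anyNA(x)) stop("missing cells are not allowed")
  row_means <- rowMeans(x)
  grand <- mean(x)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((x - row_means)^2) / (n * (k - 1))
  if (msb + msw == 0) return(NA_real_)
  (msb - msw) / (msb + (k - 1) * msw)
}

#' ICC of edge weights over common edges
#'
#' Items are the edges kept in both sessions; measurements are the NOS
#' (streamline-count) weights of those edges at scan and rescan — NOS being
#' the weight that decided which edges were retained.
#'
#' @param scan,rescan `weighted_connectome`s of the two sessions
#' @param kept_scan,kept_rescan kept `binary_edge_set`s after applying the
#'   same threshold to each session (defaults: all edges)
#' @return the ICC, or `NA` with fewer than 2 common edges
#' @export
edge_weight_icc <- function(scan, rescan,
                            kept_scan = edge_set(scan),
                            kept_rescan = edge_set(rescan)) {
  ids_a <- edge_ids(kept_scan)
  ids_b <- edge_ids(kept_rescan)
  common <- kept_scan$edges[ids_a %in% ids_b, , drop = FALSE]
  if (nrow(common) < 2L) return(NA_real_)
  icc_oneway(cbind(scan$weights$NOS[common], rescan$weights$NOS[common]))
}

#' ICC of hub scores between sessions
#'
#' Items are all `N` nodes; measurements are a node metric (degree or
#' betweenness centrality) at scan and rescan.
#'
#' @param scan_vec,rescan_vec `node_metric`s of the same metric and length
#' @return the ICC, or `NA` under degenerate variance
#' @export
hub_score_icc <- function(scan_vec, rescan_vec) {
  if (!identical(scan_vec$metric_name, rescan_vec$metric_name))
    stop("metrics differ: ", scan_vec$metric_name, " vs ",
         rescan_vec$metric_name)
  if (length(scan_vec$values) != length(rescan_vec$values))
    stop("node counts differ")
  icc_oneway(cbind(scan_vec$values, rescan_vec$values))
}

# Consistency statistics for one subject at one thresholded pair.
consistency_stats <- function(s, ta, tb, statistics) {
  out <- list()
  if ("dice" %in% statistics)
    out$dice <- dice_similarity(ta$kept, tb$kept)
  if ("icc_edge_weight" %in% statistics)
    out$icc_edge_weight <- edge_weight_icc(s$baseline, s$followup,
                                           ta$kept, tb$kept)
  if ("icc_degree" %in% statistics)
    out$icc_degree <- hub_score_icc(node_degree(ta$kept),
                                    node_degree(tb$kept))
  if ("icc_betweenness" %in% statistics)
    out$icc_betweenness <- hub_score_icc(betweenness_centrality(ta$kept),
                                         betweenness_centrality(tb$kept))
  out$n_common_edges <- sum(edge_ids(ta$kept) %in% edge_ids(tb$kept))
  out
}

ALL_CONSISTENCY_STATS <- c("dice", "icc_edge_weight", "icc_degree",
                           "icc_betweenness")

#' Scan-rescan consistency sweep over a cohort
#'
#' For every subject and threshold level, the identical threshold spec is
#' applied to baseline and follow-up, and dice similarity of edges plus the
#' ICCs of edge weight, degree and betweenness centrality are computed
#' between the two sessions. Level `NA` rows hold the unthresholded
#' statistics. The summary gives per-level mean, SD and n over subjects
#' (missing statistics excluded with counts reported), the argmax level per
#' statistic, and a paired test of each level against unthresholded.
#'
#' @param x a `cohort`
#' @param method `"fixed_density"` or `"absolute"`
#' @param levels threshold grid (default [default_grid()])
#' @param statistics subset of
#'   `c("dice", "icc_edge_weight", "icc_degree", "icc_betweenness")`
#' @param test test family for the comparison against unthresholded,
#'   `"t"` (paired two-sided t, default) or `"wilcoxon"`
#' @return list with `rows` (long per-subject table), `summary` (per level
#'   x statistic: mean, sd, n, p_vs_unthresholded) and `argmax` (level
#'   maximising the mean of each statistic)
#' @export
consistency_sweep <- function(x, method = c("fixed_density", "absolute"),
                              levels = NULL,
                              statistics = ALL_CONSISTENCY_STATS,
                              test = c("t", "wilcoxon")) {
  method <- match.arg(method)
  test <- match.arg(test)
  statistics <- match.arg(statistics, ALL_CONSISTENCY_STATS,
                          several.ok = TRUE)
  if (is.null(levels)) {
    n0 <- if (length(x$subjects)) n_nodes(x$subjects[[1L]]$baseline) else NULL
    levels <- default_grid(method, n0)
  }
  levels <- sort(levels)
  rows <- list()
  for (s in x$subjects) {
    sweep_a <- run_sweep(s$baseline, method, levels)
    sweep_b <- run_sweep(s$followup, method, levels)
    # unthresholded reference: level NA
    ua <- apply_absolute(s$baseline, 1)
    ub <- apply_absolute(s$followup, 1)
    for (li in c(0L, seq_along(levels))) {
      if (li == 0L) {
        st <- consistency_stats(s, ua, ub, statistics)
        lev <- NA_real_
        ncc <- min(ua$connected_node_count, ub$connected_node_count)
      } else {
        st <- consistency_stats(s, sweep_a[[li]], sweep_b[[li]], statistics)
        lev <- levels[li]
        ncc <- min(sweep_a[[li]]$connected_node_count,
                   sweep_b[[li]]$connected_node_count)
      }
      row <- data.frame(subject_id = s$subject_id, method = method,
                        level = lev, stringsAsFactors = FALSE)
      for (stat in statistics) row[[stat]] <- st[[stat]] %||% NA_real_
      row$n_common_edges <- st$n_common_edges
      row$connected_node_count <- ncc
      rows[[length(rows) + 1L]] <- row
    }
  }
  rows <- do.call(rbind, rows)
  summary <- summarise_consistency(rows, statistics, test)
  argmax <- stats::setNames(vapply(statistics, function(stat) {
    sub <- summary[summary$statistic == stat & !is.na(summary$level), ]
    if (!nrow(sub) || all(is.na(sub$mean))) return(NA_real_)
    sub$level[which.max(sub$mean)]
  }, 1.0), statistics)
  list(rows = rows, summary = summary, argmax = argmax,
       test = test, method = method)
}

summarise_consistency <- function(rows, statistics, test) {
  out <- list()
  lev_key <- ifelse(is.na(rows$level), "unthresholded",
                    format(rows$level, trim = TRUE))
  for (stat in statistics) {
    unthr <- rows[[stat]][is.na(rows$level)]
    names(unthr) <- rows$subject_id[is.na(rows$level)]
    for (lk in unique(lev_key)) {
      sel <- lev_key == lk
      v <- rows[[stat]][sel]
      ids <- rows$subject_id[sel]
      lev <- rows$level[sel][1L]
      p <- if (lk == "unthresholded") NA_real_ else
        compare_to_unthresholded(stats::setNames(v, ids), unthr, test)
      out[[length(out) + 1L]] <- data.frame(
        statistic = stat, level = lev,
        mean = if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
        sd = if (sum(!is.na(v)) < 2) NA_real_ else stats::sd(v, na.rm = TRUE),
        n = sum(!is.na(v)), n_missing = sum(is.na(v)),
        p_vs_unthresholded = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Paired comparison of a threshold level against unthresholded
#'
#' Two-sided paired test of the per-subject difference between a statistic
#' at one threshold level and its unthresholded value. Default is the
#' paired t-test; a Wilcoxon signed-rank alternative is available. All-zero
#' differences are reported as no effect (`p = 1`) rather than an error.
#'
#' @param at_level named per-subject values at the level
#' @param unthresholded named per-subject unthresholded values (matched by
#'   name when names are present)
#' @param test `"t"` or `"wilcoxon"`
#' @return two-sided p-value, or `NA` with fewer than 3 complete pairs
#' @export
compare_to_unthresholded <- function(at_level, unthresholded,
                                     test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (!is.null(names(at_level)) && !is.null(names(unthresholded)))
    unthresholded <- unthresholded[names(at_level)]
  ok <- !is.na(at_level) & !is.na(unthresholded)
  d <- at_level[ok] - unthresholded[ok]
  if (length(d) < 3L) return(NA_real_)
  if (all(d == 0)) return(1)
  if (stats::sd(d) == 0) return(0)  # constant nonzero shift: degenerate t
  if (test == "t") stats::t.test(d)$p.value
  else stats::wilcox.test(d, exact = FALSE)$p.value
}
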