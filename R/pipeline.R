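# Orchestration: run the full consistency + sensitivity analysis from a
# cohort directory (or in-memory cohort) and write a tabular report
# bundle, plus the command-line entry point.

#' Recommended fixed-density threshold band
#'
#' Operational rule for the band of densities to recommend: levels whose
#' mean dice similarity lies within `sd_tolerance` standard deviations of
#' the maximum mean dice AND at which every node of every subject remains
#' connected. A pure function of the consistency summary so it can be
#' tested in isolation.
#'
#' @param summary the `summary` table of [consistency_sweep()]
#' @param rows the `rows` table of the same sweep (for per-subject node
#'   counts)
#' @param n_nodes expected node count
#' @param sd_tolerance how many SDs below the maximum mean dice still
#'   count as optimal (default 1)
#' @return numeric vector of recommended levels (possibly empty)
#' @export
recommended_density_band <- function(summary, rows, n_nodes,
                                     sd_tolerance = 1) {
  dice <- summary[summary$statistic == "dice" & !is.na(summary$level), ]
  if (!nrow(dice) || all(is.na(dice$mean))) return(numeric(0))
  best <- which.max(dice$mean)
  cutoff <- dice$mean[best] - sd_tolerance * dice$sd[best]
  ok_levels <- dice$level[!is.na(dice$mean) & dice$mean >= cutoff]
  keep <- vapply(ok_levels, function(lev) {
    sub <- rows[!is.na(rows$level) & rows$level == lev, ]
    all(sub$connected_node_count == n_nodes)
  }, TRUE)
  sort(ok_levels[keep])
}

#' Run the full threshold-sweep analysis
#'
#' End-to-end orchestration: consistency sweep (dice + ICCs per level,
#' against-unthresholded tests, argmax levels), node-count curves,
#' cross-threshold correlation matrices of baseline values and of change
#' scores, per-level baseline/follow-up correlation, per-level mixed-ANOVA
#' tables, and a run-metadata record of every convention choice. All
#' tables are written as delimited text with a header row and stamped with
#' a configuration hash; two runs with equal hashes and seeds produce
#' identical bundles.
#'
#' @param x a `cohort`, or a directory path readable by [read_cohort()]
#' @param out_dir output directory for the report bundle (created); `NULL`
#'   to skip writing and only return results
#' @param method thresholding method
#' @param levels threshold grid (default [default_grid()])
#' @param metrics subject-level metrics to analyse
#' @param efficiency_convention global-efficiency convention
#' @param test test family for the against-unthresholded comparison
#' @param sd_tolerance tolerance for [recommended_density_band()]
#' @param seed seed recorded in the metadata (the analysis itself is
#'   deterministic)
#' @return list with `consistency`, `sensitivity` (one entry per metric),
#'   `recommended_band`, `metadata`
#' @export
run_full_analysis <- function(x, out_dir = NULL,
                              method = c("fixed_density", "absolute"),
                              levels = NULL,
                              metrics = c("global_efficiency",
                                          "mean_strength_FA",
                                          "mean_strength_MD"),
                              efficiency_convention = "mean_inverse",
                              test = "t",
                              sd_tolerance = 1,
                              seed = NA_integer_) {
  method <- match.arg(method)
  if (is.character(x)) x <- read_cohort(x)
  n <- n_nodes(x$subjects[[1L]]$baseline)
  if (is.null(levels)) levels <- default_grid(method, n)
  message(sprintf("run_full_analysis: %d subjects, %d nodes, %s sweep over %d levels",
                  length(x$subjects), n, method, length(levels)))
  cons <- consistency_sweep(x, method, levels, test = test)
  band <- recommended_density_band(cons$summary, cons$rows, n,
                                   sd_tolerance)
  wmh <- vapply(x$subjects, function(s) s$wmh_volume, 1.0)
  run_anova <- sum(!is.na(wmh)) >= 6
  if (!run_anova)
    message("fewer than 6 subjects with WMH volume; ANOVA stage skipped")
  sens <- list()
  for (metric in metrics) {
    sw <- sensitivity_sweep(x, metric, method, levels,
                            efficiency_convention = efficiency_convention)
    z <- longitudinal_zscores(sw$values_baseline, sw$values_followup)
    sens[[metric]] <- list(
      anova = if (run_anova) sw$anova else NULL,
      n_excluded = sw$n_excluded,
      zscores = z,
      corr_baseline = cross_threshold_correlation(sw$values_baseline),
      corr_change = cross_threshold_correlation(z$change),
      baseline_followup_r = baseline_followup_correlation(z))
  }
  config <- list(method = method, levels = levels, metrics = metrics,
                 efficiency_convention = efficiency_convention,
                 test = test, sd_tolerance = sd_tolerance,
                 icc_form = "oneway_random_single",
                 icc_pooling = "per_subject_mean",
                 zscore_sd = "sample",
                 median_split_ties = "median_to_low",
                 seed = seed)
  metadata <- list(config = config,
                   config_hash = config_hash(deparse_config(config)),
                   n_subjects = length(x$subjects),
                   n_nodes = n,
                   n_missing_wmh = sum(is.na(wmh)),
                   recommended_band = band)
  result <- list(consistency = cons, sensitivity = sens,
                 recommended_band = band, metadata = metadata)
  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  result
}

write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  h <- result$metadata$config_hash
  wt <- function(df, name) {
    df$config_hash <- h
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  wt(result$consistency$summary, "consistency_summary.csv")
  wt(result$consistency$rows, "consistency_rows.csv")
  nodes <- result$consistency$rows[
    , c("subject_id", "method", "level", "connected_node_count")]
  wt(nodes, "node_counts.csv")
  for (metric in names(result$sensitivity)) {
    s <- result$sensitivity[[metric]]
    if (!is.null(s$anova)) wt(s$anova, sprintf("anova_%s.csv", metric))
    wm <- function(m, name) {
      df <- as.data.frame(m)
      df <- cbind(level = rownames(df) %||% colnames(m), df)
      utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
    }
    wm(s$corr_baseline$r_matrix,
       sprintf("cross_threshold_baseline_%s.csv", metric))
    wm(s$corr_change$r_matrix,
       sprintf("cross_threshold_change_%s.csv", metric))
    wt(data.frame(level = names(s$baseline_followup_r),
                  r = s$baseline_followup_r, row.names = NULL),
       sprintf("baseline_followup_r_%s.csv", metric))
  }
  jsonlite::write_json(result$metadata,
                       file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(out_dir)
}

# ---------------------------------------------------------------------------
# Command-line interface

cli_usage <- function() {
  cat("usage: netsweep <command> [--key value ...]\n",
      "commands:\n",
      "  synth        --out DIR [--seed N] [--n-subjects N] [--n-nodes N]\n",
      "               [--null-effects] : generate a synthetic cohort\n",
      "  threshold    --cohort DIR --method M --level X --out DIR\n",
      "  sweep        --cohort DIR --method M [--grid a:b:step] --out FILE\n",
      "  metrics      --cohort DIR --method M --out FILE\n",
      "  consistency  --cohort DIR --method M --out DIR\n",
      "  sensitivity  --cohort DIR --method M --metric NAME --out DIR\n",
      "  run          --cohort DIR --method M --out DIR [--seed N]\n",
      "methods: fixed-density | absolute\n", sep = "")
}

parse_cli_args <- function(argv) {
  out <- list(flags = character(0))
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3L))
      if (i < length(argv) && !startsWith(argv[i + 1L], "--")) {
        out[[key]] <- argv[i + 1L]; i <- i + 2L
      } else {
        out$flags <- c(out$flags, key); i <- i + 1L
      }
    } else stop("unexpected argument: ", a)
  }
  out
}

cli_method <- function(opts) {
  m <- gsub("-", "_", opts$method %||% "fixed_density")
  match.arg(m, c("fixed_density", "absolute"))
}

#' Command-line entry point
#'
#' Subcommands: `synth` (generate a synthetic cohort directory),
#' `threshold` (apply one threshold to every session), `metrics`
#' (per-subject/level/metric long table), `consistency`, `sensitivity`,
#' and `run` (full report bundle). See `netsweep_main(c("help"))` for
#' usage. Installed as the `exec/netsweep` script.
#'
#' @param argv character vector of command-line arguments
#' @return exit status, invisibly (0 on success)
#' @export
netsweep_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv) || argv[1L] %in% c("help", "--help", "-h")) {
    cli_usage(); return(invisible(0L))
  }
  cmd <- argv[1L]
  opts <- parse_cli_args(argv[-1L])
  switch(cmd,
    synth = {
      cfg_args <- list(seed = as.integer(opts$seed %||% 1L))
      if (!is.null(opts$n_subjects))
        cfg_args$n_subjects <- as.integer(opts$n_subjects)
      if (!is.null(opts$n_nodes))
        cfg_args$n_nodes <- as.integer(opts$n_nodes)
      if ("null_effects" %in% opts$flags)
        cfg_args <- c(cfg_args, list(group_effect_fa = 0,
                                     group_effect_md = 0,
                                     group_effect_ge_proxy = 0,
                                     decline_per_followup = 0))
      cfg <- do.call(generator_config, cfg_args)
      gen <- generate_cohort(cfg)
      out <- opts$out %||% stop("--out is required")
      write_cohort(gen$cohort, out)
      gt <- gen$ground_truth
      jsonlite::write_json(
        list(true_edges = gt$true_edge_set$edges,
             groups = gt$groups, effects = gt$effects, seed = gt$seed),
        file.path(out, "ground_truth.json"),
        auto_unbox = TRUE, digits = NA)
      message("cohort written to ", out)
    },
    threshold = {
      x <- read_cohort(opts$cohort %||% stop("--cohort is required"))
      method <- cli_method(opts)
      level <- as.numeric(opts$level %||% stop("--level is required"))
      out <- opts$out %||% stop("--out is required")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      rows <- list()
      for (s in x$subjects) for (session in c("baseline", "followup")) {
        tc <- if (method == "fixed_density")
          apply_fixed_density(s[[session]], level)
        else apply_absolute(s[[session]], level)
        chans <- names(s[[session]]$weights)
        write_connectome(as_connectome(tc), stats::setNames(
          file.path(out, sprintf("%s_%s_%s.csv", s$subject_id, session,
                                 chans)), chans))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s$subject_id, session = session, method = method,
          level = level, achieved_density = tc$achieved_density,
          connected_node_count = tc$connected_node_count,
          shortfall = tc$shortfall, stringsAsFactors = FALSE)
      }
      utils::write.csv(do.call(rbind, rows),
                       file.path(out, "threshold_log.csv"),
                       row.names = FALSE)
    },
    sweep = {
      x <- read_cohort(opts$cohort %||% stop("--cohort is required"))
      method <- cli_method(opts)
      levels <- if (!is.null(opts$grid)) {
        g <- as.numeric(strsplit(opts$grid, ":", fixed = TRUE)[[1L]])
        if (length(g) != 3L || anyNA(g))
          stop("--grid must be start:stop:step")
        seq(g[1L], g[2L], by = g[3L])
      } else NULL
      rows <- list()
      for (s in x$subjects) for (session in c("baseline", "followup")) {
        for (tc in run_sweep(s[[session]], method, levels)) {
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = s$subject_id, session = session, method = method,
            level = tc$spec$level, n_edges = nrow(tc$kept$edges),
            achieved_density = tc$achieved_density,
            connected_node_count = tc$connected_node_count,
            shortfall = tc$shortfall, stringsAsFactors = FALSE)
        }
      }
      utils::write.csv(do.call(rbind, rows),
                       opts$out %||% stop("--out is required"),
                       row.names = FALSE)
    },
    metrics = {
      x <- read_cohort(opts$cohort %||% stop("--cohort is required"))
      method <- cli_method(opts)
      levels <- default_grid(method)
      rows <- list()
      for (s in x$subjects) for (session in c("baseline", "followup")) {
        for (tc in run_sweep(s[[session]], method, levels)) {
          sm <- subject_summary(tc)
          sm <- cbind(data.frame(subject_id = s$subject_id,
                                 session = session, method = method,
                                 level = tc$spec$level), sm)
          rows[[length(rows) + 1L]] <- sm
        }
      }
      utils::write.csv(do.call(rbind, rows),
                       opts$out %||% stop("--out is required"),
                       row.names = FALSE)
    },
    consistency = {
      x <- read_cohort(opts$cohort %||% stop("--cohort is required"))
      cons <- consistency_sweep(x, cli_method(opts))
      out <- opts$out %||% stop("--out is required")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(cons$rows, file.path(out, "consistency_rows.csv"),
                       row.names = FALSE)
      utils::write.csv(cons$summary,
                       file.path(out, "consistency_summary.csv"),
                       row.names = FALSE)
    },
    sensitivity = {
      x <- read_cohort(opts$cohort %||% stop("--cohort is required"))
      metric <- opts$metric %||% "global_efficiency"
      sw <- sensitivity_sweep(x, metric, cli_method(opts))
      out <- opts$out %||% stop("--out is required")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(sw$anova, file.path(out, sprintf("anova_%s.csv",
                                                        metric)),
                       row.names = FALSE)
      z <- longitudinal_zscores(sw$values_baseline, sw$values_followup)
      wm <- function(m, name) {
        df <- cbind(level = colnames(m), as.data.frame(m))
        utils::write.csv(df, file.path(out, name), row.names = FALSE)
      }
      wm(cross_threshold_correlation(sw$values_baseline)$r_matrix,
         sprintf("cross_threshold_baseline_%s.csv", metric))
      wm(cross_threshold_correlation(z$change)$r_matrix,
         sprintf("cross_threshold_change_%s.csv", metric))
      r <- baseline_followup_correlation(z)
      utils::write.csv(data.frame(level = names(r), r = r,
                                  row.names = NULL),
                       file.path(out,
                                 sprintf("baseline_followup_r_%s.csv",
                                         metric)),
                       row.names = FALSE)
    },
    run = {
      run_full_analysis(opts$cohort %||% stop("--cohort is required"),
                        out_dir = opts$out %||% stop("--out is required"),
                        method = cli_method(opts),
                        seed = as.integer(opts$seed %||% NA))
    },
    {
      cli_usage()
      stop("unknown command: ", cmd)
    })
  invisible(0L)
}
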