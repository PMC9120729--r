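# Synthetic scan-rescan cohort generator. Emulates the statistical
# structure the analysis assumes: a persistent true edge backbone with
# log-normal streamline counts, low-weight false-positive edges that are
# independent between sessions, weight-dependent false-negative dropout,
# multiplicative subject/session noise, a two-group disease effect tied to
# WMH volume, and a longitudinal decline. Ground truth is recorded so that
# recovery and calibration tests can check the pipeline end to end.

#' Generator configuration
#'
#' Defaults describe a plausible clinical diffusion-MRI cohort: 90 AAL-like
#' regions, 86 subjects, a true backbone density of 0.15 (within the 0.05 -
#' 0.30 range reported for structural connectomes), log-normal streamline
#' counts (median ~20, heavy upper tail), false-positive edges that are
#' low-weight (1-5 streamlines) and independent across sessions, and
#' dropout that hits weak edges hardest.
#'
#' Effect sizes are standardised: a group effect of `d` shifts the affected
#' channel of the high-WMH group by `d` times the corresponding
#' between-subject SD; `decline_per_followup` shifts every subject's
#' follow-up session the same way. `group_effect_ge_proxy` acts on the
#' subject-level log NOS scale, which drives global efficiency after
#' thresholding.
#'
#' @param n_nodes number of regions (default 90)
#' @param n_subjects number of subjects (default 86)
#' @param true_density density of the true backbone (default 0.15)
#' @param nos_meanlog,nos_sdlog log-normal parameters of true-edge
#'   streamline counts (counts are rounded up to >= 1)
#' @param fp_rate per-absent-pair probability of a false-positive edge per
#'   session (default 0.05)
#' @param fp_nos_range integer range of false-positive streamline counts
#'   (default 1..5, i.e. strictly below the bulk of true-edge weights)
#' @param fn_intercept,fn_slope logistic dropout of true edges:
#'   `P(drop) = plogis(fn_intercept + fn_slope * log(NOS))`; a negative
#'   slope makes weak edges drop more
#' @param session_noise_cv coefficient of variation of the multiplicative
#'   log-normal session noise on NOS
#' @param subject_scale_sd SD of the per-subject log NOS scale factor
#' @param fa_mean,fa_sd template FA distribution (clipped to (0, 1))
#' @param fa_subject_sd,fa_session_sd,fa_edge_noise_sd between-subject,
#'   between-session and per-edge FA noise SDs
#' @param md_mean,md_sd template MD distribution, mm^2/s (truncated > 0)
#' @param md_subject_sd,md_session_sd,md_edge_noise_sd MD noise SDs
#' @param group_effect_fa,group_effect_md,group_effect_ge_proxy
#'   standardised high-vs-low group effects (FA down, MD up, NOS scale
#'   down in the high group)
#' @param decline_per_followup standardised longitudinal decline applied to
#'   follow-up sessions (FA/efficiency down, MD up)
#' @param wmh_meanlog,wmh_sdlog log-normal WMH volume (ml) parameters; the
#'   high group is sampled from the upper half of the distribution so a
#'   median split recovers the groups
#' @param wmh_missing_rate fraction of subjects with missing WMH volume
#'   (default 0; such subjects are excluded from the ANOVA stage only)
#' @param followup_months_range uniform range of follow-up intervals
#' @param seed master integer seed; a hierarchical scheme derives
#'   independent streams per subject and session
#' @return object of class `generator_config`
#' @export
generator_config <- function(n_nodes = 90L, n_subjects = 86L,
                             true_density = 0.15,
                             nos_meanlog = 3, nos_sdlog = 1,
                             fp_rate = 0.05, fp_nos_range = c(1L, 5L),
                             fn_intercept = 0.5, fn_slope = -1.5,
                             session_noise_cv = 0.2,
                             subject_scale_sd = 0.15,
                             fa_mean = 0.45, fa_sd = 0.06,
                             fa_subject_sd = 0.02, fa_session_sd = 0.005,
                             fa_edge_noise_sd = 0.01,
                             md_mean = 8e-4, md_sd = 8e-5,
                             md_subject_sd = 4e-5, md_session_sd = 1e-5,
                             md_edge_noise_sd = 2e-5,
                             group_effect_fa = 0.5,
                             group_effect_md = 0.5,
                             group_effect_ge_proxy = 0.5,
                             decline_per_followup = 0.3,
                             wmh_meanlog = 2.3, wmh_sdlog = 0.8,
                             wmh_missing_rate = 0,
                             followup_months_range = c(22, 35),
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_nodes >= 3L, cfg$n_subjects >= 1L,
            cfg$true_density >= 2 / cfg$n_nodes, cfg$true_density <= 1,
            cfg$fp_rate >= 0, cfg$fp_rate <= 1,
            cfg$wmh_missing_rate >= 0, cfg$wmh_missing_rate <= 1,
            cfg$nos_sdlog > 0, cfg$session_noise_cv >= 0)
  if (stats::qlnorm(0.25, cfg$nos_meanlog, cfg$nos_sdlog) <=
      max(cfg$fp_nos_range))
    warning("false-positive weights overlap the bulk of true-edge weights; ",
            "thresholding will not separate them")
  structure(cfg, class = "generator_config")
}

#' Generate the shared true-network template
#'
#' Samples an edge set uniformly at the target density, rejecting until the
#' graph is connected, then draws template NOS (discretised log-normal,
#' >= 1), FA (normal clipped to (0, 1)) and MD (normal truncated positive)
#' weights per true edge.
#'
#' @param cfg a `generator_config`
#' @return list with `true_edges` (a `binary_edge_set`) and per-edge
#'   template weight vectors `nos`, `fa`, `md`
#' @export
generate_template <- function(cfg) {
  n <- cfg$n_nodes
  n_possible <- n * (n - 1) / 2
  m <- max(n - 1L, as.integer(round_half_up(cfg$true_density * n_possible)))
  all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  with_seed(derive_seed(cfg$seed, 0L, 1L), {
    es <- NULL
    for (try in 1:100) {
      sel <- sort(sample.int(n_possible, m))
      cand <- binary_edge_set(n, all_pairs[sel, , drop = FALSE])
      g <- es_to_igraph(cand)
      if (igraph::is_connected(g)) { es <- cand; break }
    }
    if (is.null(es)) {
      # Near tree density rejection sampling almost never hits a connected
      # graph; anchor a uniform random spanning tree and fill the rest.
      perm <- sample.int(n)
      tree <- cbind(perm[vapply(2:n, function(k)
        sample.int(k - 1L, 1L), 1L)], perm[2:n])
      tree_set <- binary_edge_set(n, tree)
      tree_ids <- (tree_set$edges[, 1] - 1L) * n + tree_set$edges[, 2]
      pair_ids <- (all_pairs[, 1] - 1L) * n + all_pairs[, 2]
      rest <- which(!pair_ids %in% tree_ids)
      extra <- sample(rest, m - (n - 1L))
      es <- binary_edge_set(n, rbind(tree_set$edges,
                                     all_pairs[extra, , drop = FALSE]))
    }
    nos <- pmax(1, round(stats::rlnorm(m, cfg$nos_meanlog, cfg$nos_sdlog)))
    fa <- pmin(1 - 1e-6, pmax(1e-6,
                              stats::rnorm(m, cfg$fa_mean, cfg$fa_sd)))
    md <- abs(stats::rnorm(m, cfg$md_mean, cfg$md_sd))
    md[md == 0] <- cfg$md_mean
    # cache the absent pairs: per-session false-positive sampling reuses it
    pair_ids <- (all_pairs[, 1] - 1L) * n + all_pairs[, 2]
    true_ids <- (es$edges[, 1] - 1L) * n + es$edges[, 2]
    absent_pairs <- all_pairs[!pair_ids %in% true_ids, , drop = FALSE]
    list(true_edges = es, nos = nos, fa = fa, md = md,
         absent_pairs = absent_pairs)
  })
}

# Per-subject latent parameters (drawn once per subject).
subject_params <- function(cfg, subject_index, group) {
  with_seed(derive_seed(cfg$seed, subject_index, 2L), {
    high <- identical(group, "high")
    list(
      # log NOS scale: group effect lowers it (proxy for lower efficiency)
      log_scale = stats::rnorm(1, 0, cfg$subject_scale_sd) -
        (if (high) cfg$group_effect_ge_proxy * cfg$subject_scale_sd else 0),
      fa_offset = stats::rnorm(1, 0, cfg$fa_subject_sd) -
        (if (high) cfg$group_effect_fa * cfg$fa_subject_sd else 0),
      md_offset = stats::rnorm(1, 0, cfg$md_subject_sd) +
        (if (high) cfg$group_effect_md * cfg$md_subject_sd else 0))
  })
}

#' Generate one session connectome
#'
#' Applies to the template, in order: weight-dependent false-negative
#' dropout of true edges; session-independent low-weight false positives;
#' subject scaling and multiplicative session noise on NOS; additive
#' subject/session/edge noise on FA and MD; and, for follow-up sessions,
#' the longitudinal decline (FA and NOS down, MD up). The result may be
#' disconnected (as real degraded scans can be); fixed-density callers
#' will then error, mirroring the method's own precondition.
#'
#' @param template output of [generate_template()]
#' @param cfg a `generator_config`
#' @param subject_index 1-based subject index (seeds the subject stream)
#' @param session `"baseline"` or `"followup"`
#' @param group `"low"`, `"high"` or `NA` (no group effect)
#' @return list with the `weighted_connectome` (`$connectome`) and ground
#'   truth bookkeeping: `dropped_edges`, `fp_edges` (index matrices)
#' @export
generate_session <- function(template, cfg, subject_index,
                             session = c("baseline", "followup"),
                             group = NA) {
  session <- match.arg(session)
  sp <- subject_params(cfg, subject_index, group)
  n <- cfg$n_nodes
  session_idx <- if (session == "baseline") 1L else 2L
  with_seed(derive_seed(cfg$seed, subject_index, 10L + session_idx), {
    te <- template$true_edges$edges
    m <- nrow(te)
    # false negatives: weaker edges drop more
    p_drop <- stats::plogis(cfg$fn_intercept +
                              cfg$fn_slope * log(template$nos))
    drop <- stats::runif(m) < p_drop
    # false positives on absent pairs, independent per session
    absent <- template$absent_pairs
    if (is.null(absent)) {
      all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      absent_id <- (all_pairs[, 1] - 1L) * n + all_pairs[, 2]
      true_id <- (te[, 1] - 1L) * n + te[, 2]
      absent <- all_pairs[!absent_id %in% true_id, , drop = FALSE]
    }
    fp <- stats::runif(nrow(absent)) < cfg$fp_rate
    fp_edges <- absent[fp, , drop = FALSE]
    n_fp <- nrow(fp_edges)
    fp_nos <- cfg$fp_nos_range[1L] - 1L +
      sample.int(cfg$fp_nos_range[2L] - cfg$fp_nos_range[1L] + 1L,
                 n_fp, replace = TRUE)
    # NOS: subject scale, session noise, longitudinal decline
    sdlog <- sqrt(log(1 + cfg$session_noise_cv^2))
    decline_log <- if (session == "followup")
      cfg$decline_per_followup * cfg$subject_scale_sd else 0
    scale <- exp(sp$log_scale - decline_log)
    noise <- stats::rlnorm(m, -sdlog^2 / 2, sdlog)
    nos_kept <- pmax(1, round(template$nos[!drop] *
                                scale * noise[!drop]))
    # FA/MD: subject offset, session offset, per-edge jitter, decline
    fa_shift <- sp$fa_offset + stats::rnorm(1, 0, cfg$fa_session_sd) -
      (if (session == "followup")
         cfg$decline_per_followup * cfg$fa_subject_sd else 0)
    md_shift <- sp$md_offset + stats::rnorm(1, 0, cfg$md_session_sd) +
      (if (session == "followup")
         cfg$decline_per_followup * cfg$md_subject_sd else 0)
    fa_kept <- pmin(1 - 1e-6, pmax(1e-6, template$fa[!drop] + fa_shift +
      stats::rnorm(sum(!drop), 0, cfg$fa_edge_noise_sd)))
    md_kept <- pmax(1e-9, template$md[!drop] + md_shift +
      stats::rnorm(sum(!drop), 0, cfg$md_edge_noise_sd))
    # false-positive FA/MD: drawn from the template distribution (their
    # weights carry no signal, only their NOS is characteristically low)
    fa_fp <- pmin(1 - 1e-6, pmax(1e-6,
      stats::rnorm(n_fp, cfg$fa_mean, cfg$fa_sd) + fa_shift))
    md_fp <- pmax(1e-9, stats::rnorm(n_fp, cfg$md_mean, cfg$md_sd) +
                    md_shift)
    ei <- rbind(te[!drop, , drop = FALSE], fp_edges)
    nos_m <- matrix(0, n, n); fa_m <- matrix(0, n, n)
    md_m <- matrix(0, n, n)
    nos_m[ei] <- c(nos_kept, fp_nos)
    fa_m[ei] <- c(fa_kept, fa_fp)
    md_m[ei] <- c(md_kept, md_fp)
    nos_m <- nos_m + t(nos_m); fa_m <- fa_m + t(fa_m)
    md_m <- md_m + t(md_m)
    list(connectome = weighted_connectome(nos_m, fa = fa_m, md = md_m),
         dropped_edges = te[drop, , drop = FALSE],
         fp_edges = fp_edges)
  })
}

#' Generate a full scan-rescan cohort with ground truth
#'
#' Subjects are split into balanced low/high groups; WMH volumes are drawn
#' from the lower/upper half of a log-normal so that the downstream median
#' split recovers the true groups. Each subject gets a baseline and a
#' follow-up session from [generate_session()].
#'
#' @param cfg a `generator_config`
#' @return list with `cohort` (a [cohort()]) and `ground_truth`: the true
#'   edge set, template weights, per-subject/session dropped and
#'   false-positive edges, group assignments, injected effect sizes and
#'   the seed
#' @export
generate_cohort <- function(cfg) {
  template <- generate_template(cfg)
  ns <- cfg$n_subjects
  groups <- rep(c("low", "high"), length.out = ns)
  meta <- with_seed(derive_seed(cfg$seed, 0L, 3L), {
    q <- stats::runif(ns)
    wmh <- stats::qlnorm(ifelse(groups == "high", 0.5 + q / 2, q / 2),
                         cfg$wmh_meanlog, cfg$wmh_sdlog)
    missing <- stats::runif(ns) < cfg$wmh_missing_rate
    wmh[missing] <- NA_real_
    fm <- stats::runif(ns, cfg$followup_months_range[1L],
                       cfg$followup_months_range[2L])
    list(wmh = wmh, followup_months = fm)
  })
  subjects <- vector("list", ns)
  gt_sessions <- vector("list", ns)
  gt_subject_params <- vector("list", ns)
  for (si in seq_len(ns)) {
    base <- generate_session(template, cfg, si, "baseline", groups[si])
    fup <- generate_session(template, cfg, si, "followup", groups[si])
    subjects[[si]] <- subject_record(
      sprintf("sub%03d", si), base$connectome, fup$connectome,
      group = groups[si], wmh_volume = meta$wmh[si],
      followup_months = meta$followup_months[si])
    gt_sessions[[si]] <- list(
      baseline = list(dropped = base$dropped_edges, fp = base$fp_edges),
      followup = list(dropped = fup$dropped_edges, fp = fup$fp_edges))
    gt_subject_params[[si]] <- subject_params(cfg, si, groups[si])
  }
  ground_truth <- list(
    true_edge_set = template$true_edges,
    template_nos = template$nos, template_fa = template$fa,
    template_md = template$md,
    sessions = gt_sessions, groups = groups,
    subject_params = gt_subject_params,
    effects = list(group_effect_fa = cfg$group_effect_fa,
                   group_effect_md = cfg$group_effect_md,
                   group_effect_ge_proxy = cfg$group_effect_ge_proxy,
                   decline_per_followup = cfg$decline_per_followup),
    seed = cfg$seed)
  list(cohort = cohort(subjects,
                       metadata = list(generator = unclass(cfg))),
       ground_truth = ground_truth)
}
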