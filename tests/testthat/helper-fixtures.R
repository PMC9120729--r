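# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Symmetric matrix from an upper-triangular edge list.
sym_from_edges <- function(n, edges, weights) {
  m <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    m[edges[r, 1], edges[r, 2]] <- weights[r]
    m[edges[r, 2], edges[r, 1]] <- weights[r]
  }
  m
}

# Random connected weighted connectome with distinct integer NOS weights
# (distinctness makes brute-force MST comparisons unambiguous where
# needed; ties are exercised separately).
random_connectome <- function(n, density = 0.6, seed = 1,
                              distinct = TRUE, channels = FALSE) {
  set.seed(seed)
  repeat {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < density
    edges <- pairs[keep, , drop = FALSE]
    if (nrow(edges) < n - 1) next
    nos <- if (distinct) sample(seq_len(1000), nrow(edges)) else
      sample(1:20, nrow(edges), replace = TRUE)
    m <- sym_from_edges(n, edges, nos)
    # connectivity check by reachability
    seen <- c(TRUE, rep(FALSE, n - 1))
    frontier <- 1L
    while (length(frontier)) {
      nb <- which(colSums(m[frontier, , drop = FALSE] > 0) > 0)
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      frontier <- new
    }
    if (all(seen)) break
  }
  fa <- md <- NULL
  if (channels) {
    fa <- sym_from_edges(n, edges, runif(nrow(edges), 0.2, 0.8))
    md <- sym_from_edges(n, edges, runif(nrow(edges), 5e-4, 1e-3))
  }
  weighted_connectome(m, fa = fa, md = md)
}

# Noise-free generator configuration: sessions reproduce the template
# exactly, so rescan == scan for every subject.
identity_generator_config <- function(n_nodes = 30, n_subjects = 6,
                                      seed = 42, ...) {
  generator_config(
    n_nodes = n_nodes, n_subjects = n_subjects, seed = seed,
    fp_rate = 0, fn_intercept = -50, fn_slope = 0,
    session_noise_cv = 0, subject_scale_sd = 0,
    fa_subject_sd = 0, fa_session_sd = 0, fa_edge_noise_sd = 0,
    md_subject_sd = 0, md_session_sd = 0, md_edge_noise_sd = 0,
    group_effect_fa = 0, group_effect_md = 0, group_effect_ge_proxy = 0,
    decline_per_followup = 0, ...)
}

# Small noisy cohort for pipeline-level tests (kept cheap).
small_cohort <- function(n_subjects = 5, n_nodes = 30, seed = 99, ...) {
  cfg <- generator_config(n_nodes = n_nodes, n_subjects = n_subjects,
                          seed = seed, true_density = 0.2, ...)
  generate_cohort(cfg)
}
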