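# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph): spanning trees by exhaustive enumeration,
# shortest paths by BFS with explicit path counting, ICC via stats::aov,
# mixed ANOVA via textbook split-plot sums of squares.

# Adjacency matrix of a binary_edge_set.
es_to_adj <- function(e) {
  a <- matrix(0L, e$n_nodes, e$n_nodes)
  if (nrow(e$edges)) {
    a[e$edges] <- 1L
    a <- a + t(a)
  }
  a
}

# All spanning trees of a small weighted graph by subset enumeration;
# returns the maximal total weight.
oracle_max_spanning_tree_weight <- function(nos) {
  n <- nrow(nos)
  idx <- which(upper.tri(nos) & nos > 0, arr.ind = TRUE)
  m <- nrow(idx)
  stopifnot(m <= 25)  # enumeration guard
  best <- -Inf
  combs <- utils::combn(m, n - 1)
  for (ci in seq_len(ncol(combs))) {
    sel <- combs[, ci]
    # acyclic + spanning check via union-find
    parent <- seq_len(n)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    ok <- TRUE
    for (e in sel) {
      ra <- find(idx[e, 1]); rb <- find(idx[e, 2])
      if (ra == rb) { ok <- FALSE; break }
      parent[ra] <- rb
    }
    if (!ok) next
    if (length(unique(vapply(seq_len(n), find, 1L))) != 1L) next
    w <- sum(nos[idx[sel, , drop = FALSE]])
    if (w > best) best <- w
  }
  best
}

# BFS distances from one source on an adjacency matrix.
oracle_bfs_dist <- function(adj, s) {
  n <- nrow(adj)
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(adj[v, ] > 0)
      new <- nb[d[nb] == Inf]
      d[new] <- d[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- unique(nxt)
  }
  d
}

# Betweenness by explicit enumeration of all shortest paths per pair,
# fractional counting, normalised by (N-1)(N-2)/2.
oracle_betweenness <- function(e) {
  adj <- es_to_adj(e)
  n <- nrow(adj)
  score <- numeric(n)
  dmat <- t(vapply(seq_len(n), function(s) oracle_bfs_dist(adj, s),
                   numeric(n)))
  enum_paths <- function(s, t) {
    # all shortest s-t paths as lists of vertices
    if (!is.finite(dmat[s, t])) return(list())
    grow <- list(s)
    for (step in seq_len(dmat[s, t])) {
      nxt <- list()
      for (p in grow) {
        v <- p[length(p)]
        for (u in which(adj[v, ] > 0))
          if (dmat[s, u] == step && dmat[u, t] == dmat[s, t] - step)
            nxt[[length(nxt) + 1L]] <- c(p, u)
      }
      grow <- nxt
    }
    grow
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- enum_paths(s, t)
    if (!length(paths)) next
    for (p in paths) {
      inner <- setdiff(p, c(s, t))
      score[inner] <- score[inner] + 1 / length(paths)
    }
  }
  score / ((n - 1) * (n - 2) / 2)
}

oracle_global_efficiency <- function(e) {
  adj <- es_to_adj(e)
  n <- nrow(adj)
  total <- 0
  for (s in seq_len(n - 1)) {
    d <- oracle_bfs_dist(adj, s)
    for (t in (s + 1):n) if (is.finite(d[t]) && d[t] > 0)
      total <- total + 1 / d[t]
  }
  total / (n * (n - 1) / 2)
}

# One-way random-effects ICC through stats::aov mean squares.
oracle_icc <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(y = as.vector(x),
                   item = factor(rep(seq_len(n), times = k)))
  tab <- summary(stats::aov(y ~ item, data = df))[[1]]
  msb <- tab["item", "Mean Sq"]
  msw <- tab["Residuals", "Mean Sq"]
  (msb - msw) / (msb + (k - 1) * msw)
}

# Textbook split-plot sums of squares for the balanced 2x2 mixed design.
# y: subjects x 2 sessions matrix; g: group factor with equal sizes.
oracle_mixed_anova_f <- function(y, g) {
  g <- as.character(g)
  stopifnot(sum(g == "low") == sum(g == "high"))
  n <- nrow(y); k <- 2
  gm <- mean(y)
  m_g <- c(tapply(rowMeans(y), g, mean))           # group means
  m_s <- colMeans(y)                               # session means
  m_gs <- rbind(low = colMeans(y[g == "low", , drop = FALSE]),
                high = colMeans(y[g == "high", , drop = FALSE]))
  n_g <- table(g)
  ss_group <- k * sum(n_g[names(m_g)] * (m_g - gm)^2)
  ss_subj <- k * sum((rowMeans(y) - m_g[g])^2)
  ss_time <- n * sum((m_s - gm)^2)
  ss_int <- sum(rep(n_g[rownames(m_gs)], k) *
                  (m_gs - outer(m_g[rownames(m_gs)], rep(1, k)) -
                     outer(rep(1, 2), m_s) + gm)^2)
  resid <- y - rowMeans(y) - m_gs[g, ] + m_g[g]
  ss_err <- sum(resid^2)
  ms_subj <- ss_subj / (n - 2)
  ms_err <- ss_err / (n - 2)
  c(time = (ss_time / 1) / ms_err,
    group = (ss_group / 1) / ms_subj,
    interaction = (ss_int / 1) / ms_err)
}
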