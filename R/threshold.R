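# MST-anchored fixed-density thresholding and absolute streamline-count
# thresholding, applied singly or as sweeps over threshold grids.

#' Threshold specification
#'
#' @param method `"fixed_density"` (target network density, backbone kept
#'   connected via the maximum spanning tree) or `"absolute"` (minimum
#'   streamline count).
#' @param level target density in `[2/N, 1]`, or minimum streamlines
#'   (>= 1).
#' @return object of class `threshold_spec`
#' @export
threshold_spec <- function(method = c("fixed_density", "absolute"), level) {
  method <- match.arg(method)
  if (method == "absolute" && level < 1)
    stop("absolute threshold level must be >= 1 streamline")
  if (method == "fixed_density" && (level <= 0 || level > 1))
    stop("fixed-density level must be a proportion in (0, 1]")
  structure(list(method = method, level = level), class = "threshold_spec")
}

# Deterministic total order over edges: NOS descending, then (i, j)
# ascending. Used both by the MST and by density filling so that kept sets
# are nested across density levels even under ties.
ranked_edges <- function(x) {
  nos <- x$weights$NOS
  idx <- which(upper.tri(nos) & nos > 0, arr.ind = TRUE)
  w <- nos[idx]
  ord <- order(-w, idx[, 1], idx[, 2])
  list(i = idx[ord, 1], j = idx[ord, 2], w = w[ord])
}

# Union-find with path halving.
uf_find <- function(parent, a) {
  while (parent[a] != a) {
    parent[a] <- parent[parent[a]]
    a <- parent[a]
  }
  a
}

#' Maximum spanning tree of the streamline-count graph
#'
#' Greedy (Kruskal-style) construction: edges are visited from highest to
#' lowest NOS and added unless they would form a cycle, yielding the
#' acyclic spanning subgraph of maximal total streamline weight. With
#' `N` connected nodes the tree has `N - 1` edges and density `2/N`.
#' Ties in NOS are broken by ascending `(i, j)` so the result is
#' deterministic.
#'
#' @param x a `weighted_connectome` whose NOS graph must be connected.
#' @return a `binary_edge_set` with exactly `N - 1` edges
#' @export
maximum_spanning_tree <- function(x) {
  n <- n_nodes(x)
  re <- ranked_edges(x)
  parent <- seq_len(n)
  keep_i <- integer(n - 1L); keep_j <- integer(n - 1L)
  k <- 0L
  for (e in seq_along(re$w)) {
    ra <- uf_find(parent, re$i[e])
    rb <- uf_find(parent, re$j[e])
    if (ra != rb) {
      parent[ra] <- rb
      k <- k + 1L
      keep_i[k] <- re$i[e]; keep_j[k] <- re$j[e]
      if (k == n - 1L) break
    }
  }
  if (k < n - 1L) {
    comp <- vapply(seq_len(n), function(v) uf_find(parent, v), 1L)
    sizes <- sort(table(comp), decreasing = TRUE)
    stop(sprintf(
      "NOS graph is disconnected (%d components of sizes %s); %s",
      length(sizes), paste(as.integer(sizes), collapse = ", "),
      "fixed-density thresholding is undefined on disconnected networks"))
  }
  binary_edge_set(n, cbind(keep_i, keep_j))
}

# Internal: returns the MST edge logical mask over ranked_edges order.
mst_mask <- function(x, re = ranked_edges(x)) {
  n <- n_nodes(x)
  parent <- seq_len(n)
  mask <- logical(length(re$w))
  k <- 0L
  for (e in seq_along(re$w)) {
    ra <- uf_find(parent, re$i[e])
    rb <- uf_find(parent, re$j[e])
    if (ra != rb) {
      parent[ra] <- rb
      mask[e] <- TRUE
      k <- k + 1L
      if (k == n - 1L) break
    }
  }
  if (k < n - 1L) {
    comp <- vapply(seq_len(n), function(v) uf_find(parent, v), 1L)
    sizes <- sort(table(comp), decreasing = TRUE)
    stop(sprintf(
      "NOS graph is disconnected (%d components of sizes %s); %s",
      length(sizes), paste(as.integer(sizes), collapse = ", "),
      "fixed-density thresholding is undefined on disconnected networks"))
  }
  mask
}

# Round half away from zero; the rounding rule for the target edge count
# must be platform-stable (base round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

new_thresholded <- function(source, spec, kept, shortfall = FALSE) {
  deg <- tabulate(c(kept$edges[, 1], kept$edges[, 2]),
                  nbins = kept$n_nodes)
  structure(list(source = source, spec = spec, kept = kept,
                 achieved_density = network_density(kept),
                 connected_node_count = sum(deg > 0L),
                 shortfall = shortfall),
            class = "thresholded_connectome")
}

#' @export
print.thresholded_connectome <- function(x, ...) {
  cat(sprintf(
    "<thresholded_connectome> %s @ %g: %d edges (density %.4f), %d/%d nodes connected%s\n",
    x$spec$method, x$spec$level, nrow(x$kept$edges), x$achieved_density,
    x$connected_node_count, n_nodes(x$source),
    if (x$shortfall) " [shortfall]" else ""))
  invisible(x)
}

#' Fixed-density thresholding anchored on the maximum spanning tree
#'
#' Starting from the MST backbone (which guarantees all `N` nodes stay
#' connected), the remaining edges are added from strongest to weakest NOS
#' until `round(target_density * N(N-1)/2)` edges are kept. If the source
#' network has fewer edges than the target (its unthresholded density is
#' below `target_density`), all edges are kept and the result carries a
#' `shortfall` flag instead of erroring, since density grids typically run
#' up to a cohort-mean density that not every subject reaches.
#'
#' @param x a `weighted_connectome` with connected NOS graph
#' @param target_density target density, at least `2/N` (the MST density)
#' @return a `thresholded_connectome`; its FA/MD channels are interpreted
#'   as masked to the kept edge set by downstream metric functions.
#' @export
apply_fixed_density <- function(x, target_density) {
  n <- n_nodes(x)
  # The canonical grid quotes the MST density rounded to 2 decimals
  # (2/90 ~= .0222 is quoted as .02), so targets down to that rounded
  # value are accepted and clamped to exactly the MST.
  min_density <- min(2 / n, round(2 / n, 2))
  if (target_density < min_density - 1e-9)
    stop(sprintf("target density %.4f is below the MST density 2/N = %.4f",
                 target_density, 2 / n))
  re <- ranked_edges(x)
  mask <- mst_mask(x, re)
  n_possible <- n * (n - 1) / 2
  target_m <- as.integer(round_half_up(target_density * n_possible))
  target_m <- max(target_m, n - 1L)   # never below the MST
  shortfall <- length(re$w) < target_m
  if (shortfall) {
    keep <- rep(TRUE, length(re$w))
  } else {
    # MST edges first, then strongest non-MST edges until the target count.
    keep <- mask
    extra <- which(!mask)[seq_len(target_m - (n - 1L))]
    keep[extra] <- TRUE
  }
  kept <- binary_edge_set(n, cbind(re$i[keep], re$j[keep]))
  new_thresholded(x, threshold_spec("fixed_density", target_density),
                  kept, shortfall)
}

#' Absolute streamline-count thresholding
#'
#' Removes every edge with fewer than `min_streamlines` streamlines
#' (edges with `NOS >= min_streamlines` are kept). Unlike the fixed-density
#' approach this gives no connectivity guarantee: nodes can become
#' disconnected, and `connected_node_count` records how many nodes retain
#' at least one edge.
#'
#' @param x a `weighted_connectome`
#' @param min_streamlines minimum streamline count (>= 1)
#' @return a `thresholded_connectome`
#' @export
apply_absolute <- function(x, min_streamlines) {
  if (min_streamlines < 1) stop("min_streamlines must be >= 1")
  n <- n_nodes(x)
  nos <- x$weights$NOS
  idx <- which(upper.tri(nos) & nos >= min_streamlines, arr.ind = TRUE)
  kept <- binary_edge_set(n, idx)
  new_thresholded(x, threshold_spec("absolute", min_streamlines), kept)
}

#' Materialise a thresholded connectome as a weighted connectome
#'
#' All weight channels are masked to the kept edge set (entries on removed
#' edges become zero). Re-thresholding the result with the same spec
#' changes nothing (idempotence).
#'
#' @param x a `thresholded_connectome`
#' @return a `weighted_connectome`
#' @export
as_connectome <- function(x) {
  stopifnot(inherits(x, "thresholded_connectome"))
  n <- n_nodes(x$source)
  mask <- matrix(FALSE, n, n)
  mask[x$kept$edges] <- TRUE
  mask <- mask | t(mask)
  w <- lapply(x$source$weights, function(m) m * mask)
  weighted_connectome(w$NOS, fa = w$FA, md = w$MD,
                      node_labels = x$source$node_labels)
}

#' Default threshold grids
#'
#' Fixed-density: densities 0.02 to 0.40 in steps of 0.01 (39 levels),
#' from the MST density `2/N` of a 90-node network up to a typical
#' cohort-mean unthresholded density. Absolute: 1 to 40 streamlines in
#' steps of 1. For networks with fewer nodes than 90 the fixed-density
#' grid is trimmed to levels at or above the rounded MST density.
#'
#' @param method `"fixed_density"` or `"absolute"`
#' @param n_nodes optional node count used to trim infeasible densities
#' @return numeric vector of levels
#' @export
default_grid <- function(method = c("fixed_density", "absolute"),
                         n_nodes = NULL) {
  method <- match.arg(method)
  if (method == "fixed_density") {
    g <- round(seq(0.02, 0.40, by = 0.01), 2)
    if (!is.null(n_nodes))
      g <- g[g >= min(2 / n_nodes, round(2 / n_nodes, 2)) - 1e-9]
    g
  } else 1:40
}

#' Apply a threshold sweep
#'
#' Applies [apply_fixed_density()] or [apply_absolute()] at every level of
#' the grid, returning results ordered by level.
#'
#' @param x a `weighted_connectome`
#' @param method thresholding method
#' @param levels grid of levels; defaults to [default_grid()]
#' @return list of `thresholded_connectome`, one per level
#' @export
run_sweep <- function(x, method = c("fixed_density", "absolute"),
                      levels = NULL) {
  method <- match.arg(method)
  if (is.null(levels)) levels <- default_grid(method, n_nodes(x))
  levels <- sort(levels)
  if (method == "fixed_density")
    lapply(levels, function(d) apply_fixed_density(x, d))
  else
    lapply(levels, function(t) apply_absolute(x, t))
}
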