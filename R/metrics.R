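# Graph metrics on (thresholded) connectomes: degree, betweenness
# centrality, global efficiency, and FA/MD-weighted node strength.
# Shortest-path machinery is delegated to igraph; the test suite checks
# every metric against exhaustive-path oracles on small graphs.

es_to_igraph <- function(e) {
  g <- igraph::make_empty_graph(n = e$n_nodes, directed = FALSE)
  if (nrow(e$edges)) g <- igraph::add_edges(g, t(e$edges))
  g
}

new_node_metric <- function(metric_name, values, undefined_nodes = integer(0)) {
  structure(list(metric_name = metric_name, values = values,
                 undefined_nodes = as.integer(undefined_nodes)),
            class = "node_metric")
}

#' Node degree
#'
#' Number of edges incident to each node.
#' @param e a `binary_edge_set`
#' @return a `node_metric` with integer values in `[0, N-1]`
#' @export
node_degree <- function(e) {
  v <- tabulate(c(e$edges[, 1], e$edges[, 2]), nbins = e$n_nodes)
  new_node_metric("degree", as.numeric(v))
}

#' Betweenness centrality
#'
#' Fraction of all shortest paths that pass through each node, computed on
#' the binary topology with fractional counting of tied shortest paths and
#' normalised by `(N-1)(N-2)/2`; node pairs in different components
#' contribute nothing.
#'
#' @param e a `binary_edge_set`
#' @return a `node_metric` with values in `[0, 1]`
#' @export
betweenness_centrality <- function(e) {
  n <- e$n_nodes
  if (!nrow(e$edges)) return(new_node_metric("betweenness", numeric(n)))
  g <- es_to_igraph(e)
  b <- igraph::betweenness(g, directed = FALSE, weights = NA)
  new_node_metric("betweenness", as.numeric(b) / ((n - 1) * (n - 2) / 2))
}

#' Global efficiency
#'
#' How efficiently information is exchanged over the network, based on
#' inverse shortest path lengths. Two conventions are implemented:
#'
#' * `"mean_inverse"` (default): mean over node pairs of `1/d(i,j)`, with
#'   disconnected pairs contributing 0. Robust to disconnection.
#' * `"inverse_mean"`: `1 / mean(d(i,j))` over connected (finite) pairs —
#'   the inverse of the characteristic path length.
#'
#' The two agree in the sense of ranking on connected regular graphs but
#' diverge on disconnected or irregular ones, so the convention used is
#' recorded in the result.
#'
#' @param e a `binary_edge_set`
#' @param weights optional symmetric matrix of positive edge weights on
#'   the kept edges; edge length is then `1/weight` (stronger edges are
#'   shorter). `NULL` for binary topology (all lengths 1).
#' @param convention efficiency convention, see above
#' @return list with `metric_name`, `value`, `node_count_used` and
#'   `convention`
#' @export
global_efficiency <- function(e, weights = NULL,
                              convention = c("mean_inverse",
                                             "inverse_mean")) {
  convention <- match.arg(convention)
  n <- e$n_nodes
  value <- if (!nrow(e$edges)) {
    0
  } else {
    g <- es_to_igraph(e)
    ew <- if (is.null(weights)) NA else {
      w <- weights[e$edges]
      if (any(w <= 0)) stop("edge weights must be positive on kept edges")
      1 / w
    }
    d <- igraph::distances(g, weights = ew)
    dv <- d[upper.tri(d)]
    if (convention == "mean_inverse") {
      inv <- ifelse(is.finite(dv) & dv > 0, 1 / dv, 0)
      mean(inv)
    } else {
      fin <- dv[is.finite(dv) & dv > 0]
      if (!length(fin)) 0 else 1 / mean(fin)
    }
  }
  list(metric_name = "global_efficiency", value = value,
       node_count_used = n, convention = convention,
       weighted = !is.null(weights))
}

#' FA/MD-weighted node strength
#'
#' Mean FA (or MD) over the kept edges incident to each node. Nodes with
#' no kept edges have undefined strength: they are listed in
#' `undefined_nodes` and excluded from downstream means, never imputed as
#' zero (a zero would conflate disconnection with low anisotropy).
#'
#' @param x a `thresholded_connectome` whose source carries the channel
#' @param channel `"FA"` or `"MD"`
#' @return a `node_metric`
#' @export
node_strength <- function(x, channel = c("FA", "MD")) {
  channel <- match.arg(channel)
  stopifnot(inherits(x, "thresholded_connectome"))
  w <- x$source$weights[[channel]]
  if (is.null(w)) stop("connectome has no ", channel, " channel")
  n <- n_nodes(x$source)
  ed <- x$kept$edges
  vals <- w[ed]
  sums <- numeric(n); cnts <- integer(n)
  if (nrow(ed)) {
    nodes <- c(ed[, 1], ed[, 2])
    agg <- rowsum(c(vals, vals), nodes)
    sums[as.integer(rownames(agg))] <- agg[, 1]
    cnts <- tabulate(nodes, nbins = n)
  }
  undef <- which(cnts == 0L)
  out <- ifelse(cnts > 0L, sums / pmax(cnts, 1L), NA_real_)
  new_node_metric(paste0("strength_", channel), out, undef)
}

#' Subject-level metric summary of a thresholded connectome
#'
#' Global efficiency plus mean FA/MD node strength (mean over nodes with at
#' least one kept edge; `node_count_used` records how many entered the
#' mean).
#'
#' @param x a `thresholded_connectome`
#' @param efficiency_convention passed to [global_efficiency()]
#' @param efficiency_weights `NULL` for binary efficiency (default) or a
#'   channel name (`"NOS"`, `"FA"`) for weighted shortest paths
#' @return data frame with columns `metric`, `value`, `node_count_used`
#' @export
subject_summary <- function(x,
                            efficiency_convention = "mean_inverse",
                            efficiency_weights = NULL) {
  w <- if (!is.null(efficiency_weights)) {
    m <- x$source$weights[[efficiency_weights]]
    if (is.null(m)) stop("no ", efficiency_weights, " channel")
    m
  }
  ge <- global_efficiency(x$kept, weights = w,
                          convention = efficiency_convention)
  rows <- data.frame(metric = "global_efficiency", value = ge$value,
                     node_count_used = ge$node_count_used,
                     stringsAsFactors = FALSE)
  for (ch in intersect(c("FA", "MD"), names(x$source$weights))) {
    s <- node_strength(x, ch)
    ok <- setdiff(seq_along(s$values), s$undefined_nodes)
    rows <- rbind(rows, data.frame(
      metric = paste0("mean_strength_", ch),
      value = if (length(ok)) mean(s$values[ok]) else NA_real_,
      node_count_used = length(ok), stringsAsFactors = FALSE))
  }
  rows
}
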