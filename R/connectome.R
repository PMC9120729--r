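# Data model, validation and delimited-text I/O for weighted connectomes
# and scan-rescan cohorts.

CHANNELS <- c("NOS", "FA", "MD")

#' Weighted structural connectome
#'
#' A weighted connectome holds one symmetric, zero-diagonal `N x N` adjacency
#' matrix per weight channel over a fixed node (brain region) order. The
#' `NOS` channel (number of streamlines) defines which edges exist: two
#' regions are connected when at least one streamline terminates in both,
#' i.e. `NOS > 0`. `FA` (fractional anisotropy, unitless in `[0, 1]`) and
#' `MD` (mean diffusivity, mm^2/s, positive) are microstructural edge
#' weights and may only be non-zero where `NOS > 0`.
#'
#' @param nos numeric `N x N` symmetric matrix of streamline counts
#'   (non-negative; fractional values are accepted with a warning since some
#'   pipelines export streamline densities).
#' @param fa optional `N x N` FA matrix, values in `[0, 1]`.
#' @param md optional `N x N` MD matrix, positive where `NOS > 0`.
#' @param node_labels character vector of `N` region names; defaults to
#'   `"node1" ... "nodeN"`.
#' @return an object of class `weighted_connectome` with elements
#'   `node_labels` and `weights` (named list of matrices).
#' @examples
#' m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 5; m[2, 3] <- m[3, 2] <- 3
#' wc <- weighted_connectome(m)
#' edge_set(wc)
#' @export
weighted_connectome <- function(nos, fa = NULL, md = NULL,
                                node_labels = NULL) {
  nos <- as.matrix(nos)
  n <- nrow(nos)
  if (is.null(node_labels)) node_labels <- paste0("node", seq_len(n))
  weights <- list(NOS = unname(nos))
  if (!is.null(fa)) weights$FA <- unname(as.matrix(fa))
  if (!is.null(md)) weights$MD <- unname(as.matrix(md))
  obj <- structure(list(node_labels = as.character(node_labels),
                        weights = weights),
                   class = "weighted_connectome")
  validate_connectome(obj)
}

#' @export
print.weighted_connectome <- function(x, ...) {
  n <- n_nodes(x)
  ne <- nrow(edge_set(x)$edges)
  cat(sprintf("<weighted_connectome> %d nodes, %d edges, channels: %s\n",
              n, ne, paste(names(x$weights), collapse = ", ")))
  invisible(x)
}

#' Number of nodes of a connectome-like object
#' @param x a `weighted_connectome` or `binary_edge_set`
#' @return integer node count
#' @export
n_nodes <- function(x) {
  if (inherits(x, "weighted_connectome")) length(x$node_labels)
  else if (inherits(x, "binary_edge_set")) x$n_nodes
  else stop("unsupported type")
}

# Validation is strict and names offending cells: silent symmetrisation
# would mask upstream export bugs.
validate_connectome <- function(x, tol = 1e-8) {
  n <- length(x$node_labels)
  if (n < 3L) stop("a connectome needs at least 3 nodes, got ", n)
  if (anyDuplicated(x$node_labels))
    stop("node labels must be unique")
  if (!"NOS" %in% names(x$weights)) stop("NOS channel is required")
  for (ch in names(x$weights)) {
    m <- x$weights[[ch]]
    if (!is.numeric(m) || nrow(m) != n || ncol(m) != n)
      stop(sprintf("%s matrix must be numeric %dx%d", ch, n, n))
    if (anyNA(m)) stop(ch, " matrix contains missing values")
    asym <- abs(m - t(m))
    if (any(asym > tol)) {
      hits <- which(asym == max(asym), arr.ind = TRUE)
      hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]  # report (i, j), i < j
      idx <- hits[1L, ]
      stop(sprintf(
        "%s matrix is asymmetric beyond tolerance %g at cell (%d, %d): %g vs %g",
        ch, tol, idx[1], idx[2], m[idx[1], idx[2]], m[idx[2], idx[1]]))
    }
    if (any(abs(diag(m)) > 0))
      stop(sprintf("%s matrix has a nonzero diagonal (node %d)",
                   ch, which(abs(diag(m)) > 0)[1L]))
  }
  nos <- x$weights$NOS
  if (any(nos < 0)) stop("NOS weights must be non-negative")
  if (any(nos != round(nos)))
    warning("fractional NOS values found; treating them as streamline densities")
  for (ch in intersect(c("FA", "MD"), names(x$weights))) {
    m <- x$weights[[ch]]
    bad <- which(m != 0 & nos == 0, arr.ind = TRUE)
    if (nrow(bad)) {
      bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
      stop(sprintf("%s is nonzero on %d edge(s) with NOS = 0, e.g. (%d, %d)",
                   ch, nrow(bad), bad[1, 1], bad[1, 2]))
    }
    if (ch == "FA" && (any(m < 0) || any(m > 1)))
      stop("FA values must lie in [0, 1]")
    if (ch == "MD" && any(m < 0))
      stop("MD values must be non-negative")
  }
  x
}

#' Binary edge set of a connectome
#'
#' Extracts the set of unordered connected node pairs: `(i, j)` is an edge
#' iff `NOS[i, j] > 0`. Pairs are stored canonically with `i < j`, ordered
#' lexicographically.
#'
#' @param x a `weighted_connectome`, or a logical/numeric adjacency matrix.
#' @return object of class `binary_edge_set`: list with `n_nodes` and
#'   `edges`, a two-column integer matrix (columns `i`, `j`, `i < j`).
#' @export
edge_set <- function(x) {
  if (inherits(x, "weighted_connectome")) {
    m <- x$weights$NOS > 0
  } else {
    m <- as.matrix(x) > 0
  }
  n <- nrow(m)
  idx <- which(upper.tri(m) & m, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  binary_edge_set(n, idx)
}

#' Construct a binary edge set from an explicit pair list
#' @param n_nodes number of nodes
#' @param edges two-column matrix of node pairs (any order); canonicalised
#'   to `i < j` and sorted.
#' @return a `binary_edge_set`
#' @export
binary_edge_set <- function(n_nodes, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(edges < 1L) || any(edges > n_nodes))
      stop("edge indices out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-pairs are not allowed")
    flip <- edges[, 1] > edges[, 2]
    edges[flip, ] <- edges[flip, 2:1]
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    if (anyDuplicated(edges)) stop("duplicate edges")
  }
  colnames(edges) <- c("i", "j")
  structure(list(n_nodes = as.integer(n_nodes), edges = edges),
            class = "binary_edge_set")
}

#' @export
print.binary_edge_set <- function(x, ...) {
  cat(sprintf("<binary_edge_set> %d nodes, %d edges\n",
              x$n_nodes, nrow(x$edges)))
  invisible(x)
}

# Scalar ids for unordered pairs, for fast set operations.
edge_ids <- function(e) {
  if (!nrow(e$edges)) return(integer(0))
  (e$edges[, 1] - 1L) * e$n_nodes + e$edges[, 2]
}

#' Network density
#'
#' The proportion of actual connections relative to all `N(N-1)/2` possible
#' connections; e.g. a density of 0.15 means 15% of all possible connections
#' were detected.
#'
#' @param e a `binary_edge_set` (or a `weighted_connectome`, converted
#'   via [edge_set()]).
#' @return density in `[0, 1]`
#' @export
network_density <- function(e) {
  if (inherits(e, "weighted_connectome")) e <- edge_set(e)
  n <- e$n_nodes
  if (n < 2L) stop("density needs at least 2 nodes")
  nrow(e$edges) / (n * (n - 1) / 2)
}

# ---------------------------------------------------------------------------
# Delimited-matrix I/O

# Autodetect comma vs tab on the first line; whitespace as fallback.
read_dense_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else
         if (grepl("\t", first, fixed = TRUE)) "\t" else ""
  m <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m))
    stop(sprintf("matrix in %s is %dx%d, expected square", path,
                 nrow(m), ncol(m)))
  m
}

#' Read a weighted connectome from delimited text matrices
#'
#' Each channel is a dense `N x N` numeric matrix in delimited text (comma
#' or tab, autodetected), without header or row names; the labels sidecar
#' has one region name per line. Validation is strict: asymmetric matrices,
#' nonzero diagonals, or FA/MD weight on absent (`NOS = 0`) edges are
#' rejected with the offending cell named, never silently repaired.
#'
#' @param matrix_paths named character vector / list mapping channel names
#'   (`NOS` required; `FA`, `MD` optional) to file paths.
#' @param labels_path optional path to the node-labels sidecar (one label
#'   per line).
#' @return a `weighted_connectome`
#' @seealso [write_connectome()]
#' @export
load_connectome <- function(matrix_paths, labels_path = NULL) {
  matrix_paths <- as.list(matrix_paths)
  if (!"NOS" %in% names(matrix_paths))
    stop("matrix_paths must include an NOS entry")
  mats <- lapply(matrix_paths, read_dense_matrix)
  labels <- if (!is.null(labels_path)) readLines(labels_path) else NULL
  if (!is.null(labels) && length(labels) != nrow(mats$NOS))
    stop(sprintf("labels file has %d lines but matrices are %dx%d",
                 length(labels), nrow(mats$NOS), nrow(mats$NOS)))
  weighted_connectome(mats$NOS, fa = mats$FA, md = mats$MD,
                      node_labels = labels)
}

#' Write a weighted connectome as delimited text matrices
#'
#' @param x a `weighted_connectome`
#' @param matrix_paths named vector/list of output paths per channel;
#'   channels without a path are skipped.
#' @param labels_path optional path for the node-labels sidecar.
#' @param sep field delimiter (default comma).
#' @return `matrix_paths`, invisibly
#' @export
write_connectome <- function(x, matrix_paths, labels_path = NULL,
                             sep = ",") {
  matrix_paths <- as.list(matrix_paths)
  if (length(matrix_paths) && is.null(names(matrix_paths)))
    stop("matrix_paths must be named by channel")
  for (ch in names(matrix_paths)) {
    if (!ch %in% names(x$weights)) next
    m <- x$weights[[ch]]
    chr <- matrix(sprintf("%.17g", m), nrow(m))  # full-precision round trip
    utils::write.table(chr, matrix_paths[[ch]], sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(labels_path)) writeLines(x$node_labels, labels_path)
  invisible(matrix_paths)
}

# ---------------------------------------------------------------------------
# Cohort: subjects x {baseline, followup}

#' Subject record with paired sessions
#'
#' @param subject_id unique subject identifier
#' @param baseline,followup `weighted_connectome`s sharing node labels
#' @param group optional `"low"`/`"high"` white-matter-hyperintensity
#'   burden label
#' @param wmh_volume WMH volume in ml, or `NA` if unavailable (such
#'   subjects are excluded from the mixed-ANOVA stage only)
#' @param followup_months follow-up interval in months
#' @return object of class `subject_record`
#' @export
subject_record <- function(subject_id, baseline, followup, group = NA,
                           wmh_volume = NA_real_,
                           followup_months = NA_real_) {
  stopifnot(inherits(baseline, "weighted_connectome"),
            inherits(followup, "weighted_connectome"))
  if (!identical(baseline$node_labels, followup$node_labels))
    stop("baseline and followup must share node labels (subject ",
         subject_id, ")")
  if (!is.na(group) && !group %in% c("low", "high"))
    stop("group must be 'low', 'high' or NA")
  structure(list(subject_id = as.character(subject_id),
                 group = group, wmh_volume = as.numeric(wmh_volume),
                 followup_months = as.numeric(followup_months),
                 baseline = baseline, followup = followup),
            class = "subject_record")
}

#' Scan-rescan cohort
#'
#' @param subjects list of `subject_record`s; all must share node labels
#'   and ids must be unique.
#' @param metadata free-form provenance list
#' @return object of class `cohort`
#' @export
cohort <- function(subjects, metadata = list()) {
  ids <- vapply(subjects, function(s) s$subject_id, "")
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  if (length(subjects)) {
    lab <- subjects[[1L]]$baseline$node_labels
    for (s in subjects)
      if (!identical(s$baseline$node_labels, lab))
        stop("all subjects must share node labels (subject ",
             s$subject_id, ")")
  }
  structure(list(subjects = subjects, metadata = metadata),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects x 2 sessions, %d nodes\n",
              length(x$subjects),
              if (length(x$subjects)) n_nodes(x$subjects[[1]]$baseline)
              else 0L))
  invisible(x)
}

#' Write a cohort to a directory (matrices + manifest)
#'
#' Layout: one delimited matrix file per subject/session/channel, a
#' `labels.txt` sidecar, and a `manifest.csv` with columns `subject_id`,
#' `session`, `group`, `wmh_volume`, `followup_months` and per-channel
#' relative paths.
#'
#' @param x a `cohort`
#' @param dir output directory (created if missing)
#' @return the manifest data frame, invisibly
#' @export
write_cohort <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  channels <- names(x$subjects[[1L]]$baseline$weights)
  writeLines(x$subjects[[1L]]$baseline$node_labels,
             file.path(dir, "labels.txt"))
  for (s in x$subjects) {
    for (session in c("baseline", "followup")) {
      conn <- s[[session]]
      paths <- stats::setNames(
        sprintf("%s_%s_%s.csv", s$subject_id, session, channels), channels)
      write_connectome(conn, stats::setNames(file.path(dir, paths),
                                             channels))
      row <- data.frame(subject_id = s$subject_id, session = session,
                        group = if (is.na(s$group)) "" else s$group,
                        wmh_volume = s$wmh_volume,
                        followup_months = s$followup_months,
                        stringsAsFactors = FALSE)
      for (ch in channels) row[[paste0(tolower(ch), "_path")]] <- paths[[ch]]
      rows[[length(rows) + 1L]] <- row
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from a manifest directory
#'
#' @param dir directory written by [write_cohort()], or containing a
#'   compatible `manifest.csv` plus `labels.txt`.
#' @return a `cohort`
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  labels_path <- file.path(dir, "labels.txt")
  if (!file.exists(labels_path)) labels_path <- NULL
  path_cols <- grep("_path$", names(manifest), value = TRUE)
  channels <- toupper(sub("_path$", "", path_cols))
  subjects <- list()
  incomplete <- character(0)
  for (id in unique(manifest$subject_id)) {
    sub <- manifest[manifest$subject_id == id, ]
    if (!all(c("baseline", "followup") %in% sub$session)) {
      incomplete <- c(incomplete, id)
      next
    }
    conns <- lapply(c("baseline", "followup"), function(session) {
      row <- sub[sub$session == session, ][1L, ]
      paths <- stats::setNames(
        file.path(dir, unlist(row[path_cols])), channels)
      load_connectome(paths, labels_path)
    })
    row <- sub[sub$session == "baseline", ][1L, ]
    grp <- row$group
    if (is.null(grp) || is.na(grp) || !nzchar(grp)) grp <- NA
    subjects[[length(subjects) + 1L]] <- subject_record(
      id, conns[[1L]], conns[[2L]], group = grp,
      wmh_volume = row$wmh_volume,
      followup_months = row$followup_months)
  }
  if (length(incomplete))
    warning(sprintf("%d subject(s) missing a session, excluded: %s",
                    length(incomplete),
                    paste(incomplete, collapse = ", ")))
  cohort(subjects, metadata = list(source_dir = dir,
                                   n_incomplete = length(incomplete)))
}
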