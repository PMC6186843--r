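# Per-subject functional connectivity: Pearson correlation networks,
# negative-edge removal, and the maximum-weight spanning tree backbone.

#' One subject's record: time series (or correlation matrix) plus label
#'
#' @param subject_id character scalar, unique within a cohort.
#' @param group group token; mapped to the positive (patient) or negative
#'   (control) class by the cohort constructor.
#' @param timeseries numeric matrix, T time points x R regions. Optional if
#'   `corr` is given; T >= 3 is required.
#' @param corr symmetric R x R correlation matrix with unit diagonal,
#'   entries in \[-1, 1\]. Optional if `timeseries` is given.
#' @return An object of class `subject_record`.
#' @export
subject_record <- function(subject_id, group, timeseries = NULL, corr = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            length(group) == 1L)
  if (is.null(timeseries) && is.null(corr))
    stop("subject ", subject_id, ": one of timeseries/corr must be supplied")
  if (!is.null(timeseries)) {
    timeseries <- as.matrix(timeseries)
    if (nrow(timeseries) < 3L)
      stop("subject ", subject_id, ": need at least 3 time points, got ",
           nrow(timeseries))
  }
  if (!is.null(corr)) {
    corr <- as.matrix(corr)
    if (nrow(corr) != ncol(corr)) stop("corr must be square")
    if (max(abs(corr - t(corr))) > 1e-10) stop("corr must be symmetric")
    if (max(abs(diag(corr) - 1)) > 1e-10) stop("corr must have unit diagonal")
    if (max(abs(corr)) > 1 + 1e-10) stop("corr entries must lie in [-1, 1]")
  }
  structure(list(subject_id = subject_id, group = as.character(group),
                 timeseries = timeseries, corr = corr),
            class = "subject_record")
}

#' Pearson correlation network from ROI time series
#'
#' Each region's time course becomes a node; the edge weight between two
#' regions is the Pearson correlation coefficient of their time courses.
#'
#' @param x a T x R numeric matrix (rows = time points, columns = regions),
#'   or a [subject_record()] carrying one.
#' @return R x R symmetric correlation matrix with unit diagonal.
#' @examples
#' ts <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 5))
#' pearson_network(ts)
#' @export
pearson_network <- function(x) {
  if (inherits(x, "subject_record")) {
    if (is.null(x$timeseries)) {
      if (!is.null(x$corr)) return(x$corr)
      stop("subject ", x$subject_id, " carries no time series")
    }
    x <- x$timeseries
  }
  x <- as.matrix(x)
  if (nrow(x) < 3L)
    stop("need at least 3 time points to estimate correlations, got ", nrow(x))
  v <- apply(x, 2L, stats::var)
  if (any(v <= 0 | !is.finite(v))) {
    bad <- which(v <= 0 | !is.finite(v))
    nm <- if (is.null(colnames(x))) as.character(bad) else colnames(x)[bad]
    stop("zero-variance ROI column(s): ", paste(nm, collapse = ", "))
  }
  r <- stats::cor(x)
  diag(r) <- 1
  (r + t(r)) / 2
}

#' Drop non-positive correlations, keeping a weighted graph
#'
#' Negative correlations are removed before tree construction (their
#' interpretation in functional networks is contested and the spanning-tree
#' backbone is defined over positive weights). Zero correlations carry no
#' connectivity information and are dropped too.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param labels optional integer node labels (default `1:R`).
#' @return A weighted [labeled_graph()] over all R nodes with one edge per
#'   strictly positive off-diagonal entry.
#' @export
correlation_graph <- function(corr, labels = NULL) {
  corr <- as.matrix(corr)
  R <- nrow(corr)
  stopifnot(R == ncol(corr))
  if (max(abs(corr - t(corr))) > 1e-10) stop("corr must be symmetric")
  if (is.null(labels)) labels <- seq_len(R)
  idx <- which(upper.tri(corr) & corr > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(labeled_graph(labels))
  labeled_graph(labels,
                cbind(labels[idx[, 1L]], labels[idx[, 2L]]),
                weights = corr[idx])
}

#' Maximum-weight spanning tree by Kruskal's procedure
#'
#' Edges are sorted into descending weight order and added greedily; an edge
#' whose addition would close a cycle is skipped. The result connects all
#' nodes acyclically with the maximum achievable total weight, giving a
#' threshold-free network backbone. Ties in weight are broken
#' deterministically in favour of the lexicographically smaller
#' (min-label, max-label) pair.
#'
#' @param g a connected weighted [labeled_graph()].
#' @return An object of classes `mst_network` and `labeled_graph` with an
#'   additional `total_weight` element; exactly `R - 1` edges.
#' @examples
#' corr <- diag(4)
#' corr[upper.tri(corr)] <- c(.9, .2, .8, .3, .1, .7)
#' corr <- corr + t(corr) - diag(diag(corr)) ; diag(corr) <- 1
#' max_spanning_tree(correlation_graph(corr))
#' @export
max_spanning_tree <- function(g) {
  stopifnot(inherits(g, "labeled_graph"))
  if (is.null(g$weights)) stop("graph must be weighted")
  n <- length(g$nodes)
  e <- g$edges
  ord <- order(-g$weights, e[, 1L], e[, 2L])
  e <- e[ord, , drop = FALSE]
  w <- g$weights[ord]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  a <- match(e[, 1L], g$nodes)
  b <- match(e[, 2L], g$nodes)
  keep <- logical(nrow(e))
  taken <- 0L
  for (k in seq_len(nrow(e))) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) {
      parent[ra] <- rb
      keep[k] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  if (taken < n - 1L) {
    roots <- vapply(seq_len(n), find, 1L)
    comps <- split(g$nodes, roots)
    stop("graph is disconnected on its positive edges; no spanning tree ",
         "exists. Components: ",
         paste(vapply(comps, function(cc)
           paste0("{", paste(cc, collapse = ","), "}"), ""), collapse = " "))
  }
  tree <- labeled_graph(g$nodes, e[keep, , drop = FALSE], weights = w[keep])
  tree$total_weight <- sum(w[keep])
  class(tree) <- c("mst_network", "labeled_graph")
  tree
}

#' @export
print.mst_network <- function(x, ...) {
  cat(sprintf("<mst_network: %d nodes, %d edges, total weight %.4f>\n",
              length(x$nodes), nrow(x$edges), x$total_weight))
  invisible(x)
}

#' Build the spanning-tree backbone for one subject
#'
#' Convenience wrapper: correlation matrix (computed from the time series if
#' absent), negative-edge removal, then [max_spanning_tree()].
#'
#' @param record a [subject_record()].
#' @return An `mst_network`.
#' @export
subject_mst <- function(record) {
  max_spanning_tree(correlation_graph(pearson_network(record)))
}
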