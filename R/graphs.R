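# Labeled undirected graphs with unique integer node labels (ROI identities).
# Edges are stored canonically: each row (min, max), rows ordered
# lexicographically, so two graphs with the same edge set compare equal.

#' Construct a labeled undirected graph
#'
#' A `labeled_graph` is an undirected graph whose nodes carry region-of-
#' interest (ROI) identities as integer labels. Within one graph every label
#' is unique, so graphs over the same atlas live in a shared label space and
#' subgraph occurrence reduces to label-pinned edge containment (see
#' [contains_subgraph()]).
#'
#' @param nodes integer vector of node labels (duplicates collapsed, sorted).
#' @param edges two-column integer matrix of label pairs, or `NULL` for an
#'   edgeless graph. Self-loops are rejected; duplicate edges collapsed.
#' @param weights optional positive numeric vector aligned with the rows of
#'   `edges` (before canonicalization).
#' @return An object of class `labeled_graph` with elements `nodes`, `edges`
#'   (canonical two-column matrix), and `weights` (or `NULL`).
#' @examples
#' g <- labeled_graph(1:4, rbind(c(1, 2), c(2, 3), c(3, 4)))
#' g
#' @export
labeled_graph <- function(nodes, edges = NULL, weights = NULL) {
  nodes <- sort(unique(as.integer(nodes)))
  if (length(nodes) == 0L) stop("a labeled_graph needs at least one node")
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
    weights <- if (is.null(weights)) NULL else numeric(0)
  } else {
    edges <- matrix(as.integer(edges), ncol = 2L)
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    if (!all(edges %in% nodes)) {
      bad <- setdiff(unique(as.vector(edges)), nodes)
      stop("edges reference labels absent from the node set: ",
           paste(bad, collapse = ", "))
    }
    lo <- pmin(edges[, 1L], edges[, 2L])
    hi <- pmax(edges[, 1L], edges[, 2L])
    ord <- order(lo, hi)
    edges <- cbind(lo, hi, deparse.level = 0L)[ord, , drop = FALSE]
    if (!is.null(weights)) {
      stopifnot(length(weights) == nrow(edges))
      weights <- as.numeric(weights)[ord]
    }
    keys <- paste(edges[, 1L], edges[, 2L], sep = "-")
    if (anyDuplicated(keys)) {
      keep <- !duplicated(keys)
      edges <- edges[keep, , drop = FALSE]
      if (!is.null(weights)) weights <- weights[keep]
    }
  }
  structure(list(nodes = nodes, edges = edges, weights = weights),
            class = "labeled_graph")
}

#' @export
print.labeled_graph <- function(x, ...) {
  cat(sprintf("<labeled_graph: %d nodes, %d edges%s>\n",
              length(x$nodes), nrow(x$edges),
              if (is.null(x$weights)) "" else ", weighted"))
  invisible(x)
}

# canonical "i-j" keys for an edge matrix or a labeled_graph
edge_keys <- function(x) {
  e <- if (inherits(x, "labeled_graph")) x$edges else x
  if (NROW(e) == 0L) return(character(0))
  paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]), sep = "-")
}

# parse "i-j" keys back to a canonical edge matrix
keys_to_edges <- function(keys) {
  if (length(keys) == 0L) return(matrix(integer(0), ncol = 2L))
  parts <- strsplit(keys, "-", fixed = TRUE)
  m <- cbind(as.integer(vapply(parts, `[`, "", 1L)),
             as.integer(vapply(parts, `[`, "", 2L)))
  m[order(m[, 1L], m[, 2L]), , drop = FALSE]
}

#' Test label-pinned subgraph containment
#'
#' Because node labels are unique within any graph, label-preserving
#' subgraph isomorphism degenerates to containment: `pattern` occurs in
#' `host` exactly when every pattern node label is a host node and every
#' pattern edge (as an unordered label pair) is a host edge.
#'
#' @param host,pattern `labeled_graph` objects sharing one label space.
#' @return `TRUE` or `FALSE`.
#' @examples
#' host <- labeled_graph(1:4, rbind(c(1, 2), c(2, 3), c(3, 4)))
#' contains_subgraph(host, labeled_graph(2:3, rbind(c(2, 3))))
#' @export
contains_subgraph <- function(host, pattern) {
  stopifnot(inherits(host, "labeled_graph"), inherits(pattern, "labeled_graph"))
  all(pattern$nodes %in% host$nodes) &&
    all(edge_keys(pattern) %in% edge_keys(host))
}

# connected components of a labeled_graph; returns list of label vectors
graph_components <- function(g) {
  n <- length(g$nodes)
  idx <- match
  comp <- seq_len(n)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(g$edges) > 0L) {
    a <- match(g$edges[, 1L], g$nodes)
    b <- match(g$edges[, 2L], g$nodes)
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  unname(split(g$nodes, roots))
}

is_connected_graph <- function(g) length(graph_components(g)) == 1L
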