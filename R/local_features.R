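# Local property of the spanning-tree network: node betweenness, the
# two-sample t-test region selection, and the linear (vector) kernel.

#' Betweenness centrality of every node of a tree
#'
#' On a tree the path between any two nodes is unique, so the betweenness of
#' node i is the fraction of ordered node pairs (h, j), with h, j, i all
#' distinct, whose path passes through i as an interior node, normalized by
#' (n-1)(n-2). Values lie in \[0, 1\]; leaves score exactly 0.
#'
#' Computed from branch sizes: removing i splits the tree into components of
#' sizes c_1..c_d, and the number of ordered pairs avoiding i is
#' sum c_k (c_k - 1).
#'
#' @param tree an `mst_network` (or any connected acyclic [labeled_graph()])
#'   with at least 3 nodes.
#' @return Named numeric vector, one entry per node label.
#' @examples
#' star <- labeled_graph(1:4, rbind(c(1, 2), c(1, 3), c(1, 4)))
#' tree_betweenness(star)  # centre 1, leaves 0
#' @export
tree_betweenness <- function(tree) {
  stopifnot(inherits(tree, "labeled_graph"))
  n <- length(tree$nodes)
  if (n < 3L) stop("betweenness normalization needs at least 3 nodes, got ", n)
  if (nrow(tree$edges) != n - 1L)
    stop("not a tree: ", nrow(tree$edges), " edges for ", n, " nodes")
  a <- match(tree$edges[, 1L], tree$nodes)
  b <- match(tree$edges[, 2L], tree$nodes)
  adj <- vector("list", n)
  for (k in seq_along(a)) {
    adj[[a[k]]] <- c(adj[[a[k]]], b[k])
    adj[[b[k]]] <- c(adj[[b[k]]], a[k])
  }
  # BFS order from node 1, then subtree sizes in reverse (post-) order
  parent <- integer(n)
  order_ <- integer(n)
  seen <- logical(n)
  seen[1L] <- TRUE
  order_[1L] <- 1L
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- order_[head]
    for (u in adj[[v]]) {
      if (!seen[u]) {
        seen[u] <- TRUE
        parent[u] <- v
        tail <- tail + 1L
        order_[tail] <- u
      }
    }
    head <- head + 1L
  }
  if (tail < n) stop("tree is disconnected")
  size <- rep(1L, n)
  for (k in rev(seq_len(n)[-1L])) {
    v <- order_[k]
    size[parent[v]] <- size[parent[v]] + size[v]
  }
  denom <- (n - 1) * (n - 2)
  bc <- numeric(n)
  for (v in seq_len(n)) {
    branches <- size[adj[[v]][adj[[v]] != parent[v] | v == 1L]]
    if (v != 1L) branches <- c(branches, n - size[v])
    bc[v] <- (denom - sum(branches * (branches - 1))) / denom
  }
  names(bc) <- tree$nodes
  bc
}

#' Select discriminative regions by a two-sample t-test
#'
#' For each region, the two groups' betweenness values are compared with a
#' two-sided two-sample t-test (pooled variance by default, the classical
#' reading; Welch via `welch = TRUE`); regions with p below `alpha` are
#' selected. A region with (near-)zero pooled variance is assigned p = 1 and
#' never selected. If no region passes, all regions are retained with a
#' warning so the downstream kernel is still defined.
#'
#' @param B numeric matrix of features, rows = subjects, columns = regions
#'   (column names = region labels).
#' @param y logical or factor group indicator (`TRUE`/second level =
#'   positive class); at least 2 subjects per class.
#' @param alpha significance level, default 0.05.
#' @param welch use Welch's unequal-variance test instead of pooled.
#' @return Object of class `region_selection`: list with `selected`
#'   (ascending region labels), `pvalues`, `alpha`, `fallback` (logical).
#' @export
select_regions <- function(B, y, alpha = 0.05, welch = FALSE) {
  B <- as.matrix(B)
  pos <- as.logical(if (is.factor(y)) y == levels(y)[2L] else y)
  if (sum(pos) < 2L || sum(!pos) < 2L)
    stop("each class needs at least 2 subjects (got ", sum(pos), " / ",
         sum(!pos), ")")
  labels <- colnames(B)
  if (is.null(labels)) labels <- as.character(seq_len(ncol(B)))
  pv <- vapply(seq_len(ncol(B)), function(j) {
    x1 <- B[pos, j]; x0 <- B[!pos, j]
    if (stats::var(x1) + stats::var(x0) < 1e-24) return(1)
    tryCatch(stats::t.test(x1, x0, var.equal = !welch)$p.value,
             error = function(e) 1)
  }, numeric(1))
  names(pv) <- labels
  sel <- which(pv < alpha)
  fallback <- length(sel) == 0L
  if (fallback) {
    warning("no region passed alpha = ", alpha,
            "; falling back to all regions")
    sel <- seq_len(ncol(B))
  }
  lab_sel <- labels[sort(sel)]
  num <- suppressWarnings(as.integer(lab_sel))
  if (!anyNA(num)) lab_sel <- num
  structure(list(selected = lab_sel, pvalues = pv,
                 alpha = alpha, fallback = fallback),
            class = "region_selection")
}

#' @export
print.region_selection <- function(x, ...) {
  cat(sprintf("<region_selection: %d of %d regions at alpha = %g%s>\n",
              length(x$selected), length(x$pvalues), x$alpha,
              if (x$fallback) " (fallback: none significant)" else ""))
  invisible(x)
}

#' Linear kernel between two feature vectors
#'
#' The local-property similarity of two networks is the plain inner product
#' of their (selection-restricted) betweenness vectors.
#'
#' @param x,y numeric vectors of equal length.
#' @return A scalar.
#' @examples
#' linear_kernel(c(1, 2, 3), c(4, 5, 6))  # 32
#' @export
linear_kernel <- function(x, y) {
  if (length(x) != length(y))
    stop("feature vectors differ in length (", length(x), " vs ",
         length(y), ")")
  sum(as.numeric(x) * as.numeric(y))
}

#' Linear kernel matrix over rows of a feature matrix
#'
#' @param X numeric matrix, rows = subjects (optionally row-named).
#' @param Y optional second matrix for a cross block (rows of `X` vs rows of
#'   `Y`); defaults to `X`.
#' @return Kernel matrix `X %*% t(Y)`.
#' @export
linear_kernel_matrix <- function(X, Y = X) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("feature matrices differ in width")
  K <- tcrossprod(X, Y)
  dimnames(K) <- list(rownames(X), rownames(Y))
  K
}
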