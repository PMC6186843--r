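# Weisfeiler-Lehman subtree kernel over (reconstructed) networks.
#
# Initial node labels are node degrees (ROI identity is deliberately
# discarded here; it already entered through subgraph selection). Each
# refinement iteration augments a node's label with the sorted multiset of
# its neighbours' labels and compresses the augmented string to a dense
# integer id through a shared vocabulary. The kernel is the inner product
# of label-count vectors accumulated over iterations 0..h.

#' Weisfeiler-Lehman feature maps for a graph collection
#'
#' @param graphs list of [labeled_graph()] objects.
#' @param h number of refinement iterations (>= 0); counts from iterations
#'   0..h are concatenated.
#' @param vocab optional frozen vocabulary (named integer vector as returned
#'   in `$vocab`) from a previous call, e.g. the training collection;
#'   augmented labels unseen there receive fresh ids that cannot collide
#'   with existing ones, so train-test kernel blocks stay well defined.
#' @return Object of class `wl_feature_maps`: list with `features` (sparse
#'   graph x label-id count matrix), `vocab` (named integer vector mapping
#'   "iteration|augmented label" strings to ids), `h`.
#' @examples
#' p3 <- labeled_graph(1:3, rbind(c(1, 2), c(2, 3)))
#' fm <- wl_feature_maps(list(p3), h = 0)
#' as.matrix(fm$features)  # two degree-1 nodes, one degree-2 node
#' @export
wl_feature_maps <- function(graphs, h, vocab = NULL) {
  stopifnot(is.numeric(h), length(h) == 1L, h >= 0, h == floor(h))
  env <- new.env(parent = emptyenv(), hash = TRUE)
  nextid <- 1L
  if (!is.null(vocab) && length(vocab)) {
    for (k in seq_along(vocab)) assign(names(vocab)[k], vocab[[k]], envir = env)
    nextid <- max(vocab) + 1L
  }
  lookup <- function(keys) {
    ids <- integer(length(keys))
    for (k in seq_along(keys)) {
      id <- env[[keys[k]]]
      if (is.null(id)) {
        id <- nextid
        nextid <<- nextid + 1L
        assign(keys[k], id, envir = env)
      }
      ids[k] <- id
    }
    ids
  }
  ti <- integer(0); tj <- integer(0); tx <- integer(0)
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    nv <- length(g$nodes)
    adj <- vector("list", nv)
    if (nrow(g$edges) > 0L) {
      a <- match(g$edges[, 1L], g$nodes)
      b <- match(g$edges[, 2L], g$nodes)
      for (k in seq_along(a)) {
        adj[[a[k]]] <- c(adj[[a[k]]], b[k])
        adj[[b[k]]] <- c(adj[[b[k]]], a[k])
      }
    }
    deg <- lengths(adj)
    lab <- lookup(paste0("0|", deg))
    counts <- table(lab)
    for (it in seq_len(h)) {
      keys <- vapply(seq_len(nv), function(v)
        paste0(it, "|", lab[v], "|",
               paste(sort(lab[adj[[v]]]), collapse = ",")), "")
      lab <- lookup(keys)
      counts <- c(counts, table(lab))
    }
    ids <- as.integer(names(counts))
    ti <- c(ti, rep.int(gi, length(ids)))
    tj <- c(tj, ids)
    tx <- c(tx, as.integer(counts))
  }
  vocab_out <- unlist(as.list(env))
  vocab_out <- vocab_out[order(vocab_out)]
  Phi <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                              dims = c(length(graphs), nextid - 1L))
  structure(list(features = Phi, vocab = vocab_out, h = h),
            class = "wl_feature_maps")
}

#' @export
print.wl_feature_maps <- function(x, ...) {
  cat(sprintf("<wl_feature_maps: %d graphs, %d labels, h = %d>\n",
              nrow(x$features), ncol(x$features), x$h))
  invisible(x)
}

#' Weisfeiler-Lehman subtree kernel matrix
#'
#' `K[i, j]` is the inner product of graphs i and j's label-count feature
#' vectors accumulated over h refinement iterations; symmetric and positive
#' semidefinite by construction.
#'
#' @inheritParams wl_feature_maps
#' @param ids optional subject ids used as dimnames.
#' @return Dense symmetric kernel matrix.
#' @export
wl_kernel_matrix <- function(graphs, h, ids = NULL) {
  fm <- wl_feature_maps(graphs, h)
  K <- as.matrix(Matrix::tcrossprod(fm$features))
  dimnames(K) <- list(ids, ids)
  K
}

#' Cross kernel block between two WL feature-map sets
#'
#' The second set is expected to extend the first's vocabulary (see the
#' `vocab` argument of [wl_feature_maps()]); feature matrices are padded
#' with zero columns so inner products run over the shared vocabulary.
#'
#' @param fm_a,fm_b `wl_feature_maps` objects.
#' @return `nrow(a) x nrow(b)` matrix of inner products.
#' @export
wl_cross_kernel <- function(fm_a, fm_b) {
  d <- max(ncol(fm_a$features), ncol(fm_b$features))
  pad <- function(Phi) {
    if (ncol(Phi) == d) return(Phi)
    Matrix::cbind2(Phi, Matrix::Matrix(0, nrow(Phi), d - ncol(Phi),
                                       sparse = TRUE))
  }
  as.matrix(Matrix::tcrossprod(pad(fm_a$features), pad(fm_b$features)))
}
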