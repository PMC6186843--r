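# The fitting surface: a cohort container of per-subject tree backbones,
# and mstmkl(), the multikernel classifier fit on a training cohort.

#' Build a cohort of spanning-tree networks from subject records
#'
#' Computes, for every subject, the Pearson correlation network, removes
#' negative edges, constructs the maximum spanning tree, and extracts node
#' betweenness. These per-subject transforms are label-free, so a cohort
#' can be built once and subset per cross-validation fold without leakage.
#'
#' @param records list of [subject_record()] objects.
#' @param positive_label the group token treated as the patient (positive)
#'   class; sensitivity/specificity are defined with respect to it.
#' @return Object of class `mst_cohort`: list with `ids`, `y` (factor,
#'   second level = positive), `msts` (list of `mst_network`), `B`
#'   (subjects x regions betweenness matrix), `R`, `positive`.
#' @export
mst_cohort <- function(records, positive_label) {
  stopifnot(length(records) >= 1L)
  ids <- vapply(records, function(r) r$subject_id, "")
  if (anyDuplicated(ids))
    stop("duplicate subject_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  groups <- vapply(records, function(r) r$group, "")
  tokens <- sort(unique(groups))
  if (length(tokens) != 2L)
    stop("expected exactly 2 group tokens, found: ",
         paste(tokens, collapse = ", "))
  if (!positive_label %in% tokens)
    stop("positive_label '", positive_label, "' is not among the group ",
         "tokens: ", paste(tokens, collapse = ", "))
  y <- factor(groups, levels = c(setdiff(tokens, positive_label),
                                 positive_label))
  msts <- lapply(records, subject_mst)
  Rn <- unique(vapply(msts, function(g) length(g$nodes), 1L))
  if (length(Rn) != 1L)
    stop("subjects disagree on the number of regions: ",
         paste(Rn, collapse = ", "))
  B <- t(vapply(msts, tree_betweenness, numeric(Rn)))
  rownames(B) <- ids
  structure(list(ids = ids, y = y, msts = msts, B = B, R = Rn,
                 positive = positive_label),
            class = "mst_cohort")
}

#' @export
`[.mst_cohort` <- function(x, i) {
  structure(list(ids = x$ids[i], y = x$y[i], msts = x$msts[i],
                 B = x$B[i, , drop = FALSE], R = x$R,
                 positive = x$positive),
            class = "mst_cohort")
}

#' @export
length.mst_cohort <- function(x) length(x$ids)

#' @export
print.mst_cohort <- function(x, ...) {
  cat(sprintf("<mst_cohort: %d subjects (%d %s / %d %s), %d regions>\n",
              length(x$ids), sum(x$y == levels(x$y)[2L]), levels(x$y)[2L],
              sum(x$y == levels(x$y)[1L]), levels(x$y)[1L], x$R))
  invisible(x)
}

# stratified fold assignment; guarantees both classes in every training set
stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

# inner cross-validated accuracy over the beta grid; ties -> smallest beta
select_beta <- function(Kv, Kg, y, grid, C, inner_folds, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  fold <- stratified_folds(y, inner_folds)
  acc <- vapply(grid, function(b) {
    K <- fuse_kernels(Kv, Kg, b)
    hits <- 0L
    for (f in seq_len(inner_folds)) {
      tr <- fold != f; te <- !tr
      if (!any(te)) next
      m <- svm_train(K[tr, tr, drop = FALSE], y[tr], C = C)
      p <- svm_predict(m, K[te, tr, drop = FALSE])
      hits <- hits + sum(p$predicted == y[te])
    }
    hits / length(y)
  }, numeric(1))
  list(beta = grid[which.max(acc)], accuracy = acc)
}

#' Fit the multikernel spanning-tree network classifier
#'
#' Fits the full pipeline on a training cohort: two-sample t-test region
#' selection on betweenness (linear kernel, the local property); per-group
#' frequent-subgraph mining, frequency-difference selection, network
#' reconstruction and the Weisfeiler-Lehman subtree kernel (the
#' topological property); kernel normalization; fusion with weight `beta`
#' (selected by inner cross-validation when `"auto"`); and a soft-margin
#' SVM on the fused kernel. Everything supervised is computed from the
#' supplied cohort only, so held-out subjects can be scored without leakage
#' via [predict.mstmkl()].
#'
#' @param cohort an [mst_cohort()] (the training subjects).
#' @param support minimum subgraph frequency s in (0, 1]; default 0.7.
#' @param threshold frequency-difference threshold T (strict >); default
#'   0.13. (0.5 can serve as a conservative reference value.)
#' @param h Weisfeiler-Lehman iterations; default 2.
#' @param alpha t-test significance level; default 0.05.
#' @param beta `"auto"` (inner-CV grid search) or a fixed value in \[0, 1\].
#' @param beta_grid candidate weights for `"auto"`; default 0, 0.1, ..., 1.
#' @param C SVM soft-margin cost; default 1.
#' @param pattern_mode `"maximal"` (default) or `"all"` frequent patterns.
#' @param method `"mkl"` (fused, default), `"lp"` (linear kernel only) or
#'   `"tp"` (graph kernel only); the single-kernel methods are the
#'   pipeline's ablation baselines and coincide with `beta` fixed at 1 or 0.
#' @param inner_folds folds for the inner beta search; default 5.
#' @param seed integer seed for the inner-fold shuffle (restored on exit).
#' @param welch use Welch's t-test for region selection.
#' @param max_patterns safety bound passed to [mine_frequent_subgraphs()].
#' @return Object of class `mstmkl`.
#' @export
mstmkl <- function(cohort, support = 0.7, threshold = 0.13, h = 2,
                   alpha = 0.05, beta = "auto",
                   beta_grid = seq(0, 1, by = 0.1), C = 1,
                   pattern_mode = c("maximal", "all"),
                   method = c("mkl", "lp", "tp"),
                   inner_folds = 5, seed = 1, welch = FALSE,
                   max_patterns = 1e5) {
  stopifnot(inherits(cohort, "mst_cohort"))
  pattern_mode <- match.arg(pattern_mode)
  method <- match.arg(method)
  y <- cohort$y
  if (sum(y == levels(y)[2L]) < 2L || sum(y == levels(y)[1L]) < 2L)
    stop("each class needs at least 2 training subjects")
  fit <- list(ids = cohort$ids, y = y, positive = cohort$positive,
              method = method,
              params = list(support = support, threshold = threshold, h = h,
                            alpha = alpha, C = C,
                            pattern_mode = pattern_mode, welch = welch))

  Kv <- Kg <- NULL
  if (method != "tp") {
    sel <- select_regions(cohort$B, y, alpha = alpha, welch = welch)
    X <- cohort$B[, as.character(sel$selected), drop = FALSE]
    dv <- rowSums(X^2)
    Kv <- normalize_kernel_safe(structure(
      tcrossprod(X), dimnames = list(cohort$ids, cohort$ids)))
    fit$selection <- sel
    fit$n_significant <- if (sel$fallback) 0L else length(sel$selected)
    fit$X <- X
    fit$diag_v <- dv
  }
  if (method != "lp") {
    pos <- y == levels(y)[2L]
    mined <- c(
      mine_frequent_subgraphs(cohort$msts[pos], s = support,
                              mode = pattern_mode,
                              source_group = levels(y)[2L],
                              max_patterns = max_patterns),
      mine_frequent_subgraphs(cohort$msts[!pos], s = support,
                              mode = pattern_mode,
                              source_group = levels(y)[1L],
                              max_patterns = max_patterns))
    scored <- score_patterns(mined, cohort$msts[pos], cohort$msts[!pos])
    selected <- select_discriminative(scored, threshold)
    if (length(selected) == 0L)
      warning("no discriminative subgraph exceeds threshold ", threshold,
              "; reconstructed networks are edgeless")
    recon <- reconstruct_networks(cohort$msts, selected)
    fm <- wl_feature_maps(recon, h)
    Kg <- normalize_kernel_safe(structure(
      as.matrix(Matrix::tcrossprod(fm$features)),
      dimnames = list(cohort$ids, cohort$ids)))
    fit$patterns <- selected
    fit$n_patterns_mined <- length(scored)
    fit$wl_train <- fm
    fit$diag_g <- Matrix::rowSums(fm$features^2)
  }

  if (method == "lp") {
    fit$beta <- 1
    K <- Kv
  } else if (method == "tp") {
    fit$beta <- 0
    K <- Kg
  } else {
    if (identical(beta, "auto")) {
      bsel <- select_beta(Kv, Kg, y, beta_grid, C, inner_folds, seed)
      fit$beta <- bsel$beta
      fit$beta_accuracy <- stats::setNames(bsel$accuracy, beta_grid)
    } else {
      if (!is.numeric(beta) || beta < 0 || beta > 1)
        stop("beta must be 'auto' or a number in [0, 1]")
      fit$beta <- beta
    }
    K <- fuse_kernels(Kv, Kg, fit$beta)
  }
  fit$svm <- svm_train(K, y, C = C)
  class(fit) <- "mstmkl"
  fit
}

#' Predict group membership for held-out subjects
#'
#' Scores new subjects against a fitted model using only training-derived
#' quantities: the training fold's region selection, discriminative
#' patterns, frozen Weisfeiler-Lehman vocabulary, fusion weight and support
#' vectors.
#'
#' @param object a fitted [mstmkl()] model.
#' @param newdata an [mst_cohort()] of held-out subjects (labels, if
#'   present, are ignored).
#' @param ... unused.
#' @return Data frame with columns `subject_id`, `predicted` (factor with
#'   the training levels) and `score` (decision value, higher = more
#'   patient-like).
#' @export
predict.mstmkl <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "mst_cohort"))
  Kvc <- Kgc <- NULL
  if (object$method != "tp") {
    Xn <- newdata$B[, colnames(object$X), drop = FALSE]
    Kvc <- normalize_cross_kernel(tcrossprod(Xn, object$X),
                                  rowSums(Xn^2), object$diag_v)
  }
  if (object$method != "lp") {
    recon <- reconstruct_networks(newdata$msts, object$patterns)
    fm <- wl_feature_maps(recon, object$params$h,
                          vocab = object$wl_train$vocab)
    Kgc <- normalize_cross_kernel(wl_cross_kernel(fm, object$wl_train),
                                  Matrix::rowSums(fm$features^2),
                                  object$diag_g)
  }
  Kc <- if (object$method == "lp") Kvc
        else if (object$method == "tp") Kgc
        else fuse_kernels(Kvc, Kgc, object$beta)
  out <- svm_predict(object$svm, Kc)
  data.frame(subject_id = newdata$ids, predicted = out$predicted,
             score = out$scores, row.names = NULL)
}

#' @export
print.mstmkl <- function(x, ...) {
  cat(sprintf("<mstmkl fit: %d subjects, method %s, beta = %g>\n",
              length(x$ids), x$method, x$beta))
  if (!is.null(x$selection))
    cat(sprintf("  regions selected: %d (alpha = %g%s)\n",
                length(x$selection$selected), x$selection$alpha,
                if (x$selection$fallback) ", fallback" else ""))
  if (!is.null(x$patterns))
    cat(sprintf("  discriminative subgraphs: %d (of %d scored patterns)\n",
                length(x$patterns), x$n_patterns_mined))
  invisible(x)
}

#' @export
summary.mstmkl <- function(object, ...) {
  print(object)
  if (!is.null(object$selection)) {
    cat("  selected region labels: ",
        paste(object$selection$selected, collapse = ", "), "\n", sep = "")
  }
  if (!is.null(object$patterns) && length(object$patterns)) {
    cat("  subgraph edge sets:\n")
    for (p in object$patterns)
      cat(sprintf("    {%s}  diff = %.3f (%s)\n",
                  paste(edge_keys(p$edges), collapse = " "),
                  p$freq_diff, p$source_group))
  }
  if (!is.null(object$beta_accuracy)) {
    cat("  inner-CV accuracy over beta grid:\n")
    print(round(object$beta_accuracy, 3))
  }
  invisible(object)
}
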