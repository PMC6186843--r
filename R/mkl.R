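# Kernel normalization, multikernel fusion, classification metrics, and a
# thin wrapper around the support vector machine on precomputed kernels.

#' Cosine-normalize a kernel matrix
#'
#' `K'[i, j] = K[i, j] / sqrt(K[i, i] K[j, j])`; the diagonal becomes 1 and
#' positive semidefiniteness is preserved. The two kernel types are
#' normalized individually before fusion so neither scale dominates.
#'
#' @param K symmetric kernel matrix with strictly positive diagonal.
#' @return Normalized kernel matrix.
#' @export
normalize_kernel <- function(K) {
  K <- as.matrix(K)
  d <- diag(K)
  if (any(d <= 0)) {
    bad <- which(d <= 0)
    nm <- if (is.null(rownames(K))) as.character(bad) else rownames(K)[bad]
    stop("kernel diagonal must be strictly positive; offending subject(s): ",
         paste(nm, collapse = ", "))
  }
  s <- 1 / sqrt(d)
  Kn <- K * tcrossprod(s)
  diag(Kn) <- 1
  dimnames(Kn) <- dimnames(K)
  Kn
}

# pipeline-internal tolerant variant: a subject with zero self-similarity
# (e.g. all selected regions are leaves of its tree) carries no signal; it
# gets unit self-similarity and zero similarity to everyone else, which
# keeps the matrix PSD (the zero vector is replaced by a fresh orthonormal
# direction). The exported normalize_kernel() keeps the strict error.
normalize_kernel_safe <- function(K) {
  d <- diag(K)
  zero <- d <= 0
  if (!any(zero)) return(normalize_kernel(K))
  warning(sum(zero), " subject(s) with zero kernel self-similarity; ",
          "treated as orthogonal to all others")
  s <- 1 / sqrt(ifelse(zero, 1, d))
  Kn <- K * tcrossprod(s)
  Kn[zero, ] <- 0
  Kn[, zero] <- 0
  diag(Kn) <- 1
  dimnames(Kn) <- dimnames(K)
  Kn
}

# cross-block analogue: entries divided by sqrt(self-similarities); a test
# subject with zero self-similarity gets similarity 0 with a warning
normalize_cross_kernel <- function(Kc, diag_rows, diag_cols) {
  zr <- diag_rows <= 0
  if (any(zr)) {
    warning(sum(zr), " subject(s) with zero self-similarity; their ",
            "normalized similarities are set to 0")
    diag_rows[zr] <- 1
  }
  zc <- diag_cols <= 0
  diag_cols[zc] <- 1
  Kn <- Kc * tcrossprod(1 / sqrt(diag_rows), 1 / sqrt(diag_cols))
  Kn[zr, ] <- 0
  Kn[, zc] <- 0
  Kn
}

#' Fuse two normalized kernels with weight beta
#'
#' Elementwise convex combination `beta * Kv + (1 - beta) * Kg` of the
#' linear (local-property) kernel and the graph (topological) kernel;
#' positive semidefinite as a convex combination of PSD matrices.
#'
#' @param Kv,Kg kernel matrices with identical dimensions and subject order.
#' @param beta weight in \[0, 1\]; `beta = 1` keeps only the linear kernel,
#'   `beta = 0` only the graph kernel.
#' @return Fused kernel matrix.
#' @export
fuse_kernels <- function(Kv, Kg, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta > 1)
    stop("beta must be a scalar in [0, 1], got ", beta)
  if (!all(dim(Kv) == dim(Kg))) stop("kernel dimensions differ")
  beta * Kv + (1 - beta) * Kg
}

#' Classification metrics: accuracy, sensitivity, specificity, AUC
#'
#' Sensitivity is the true-positive rate with respect to the patient
#' (positive) class, specificity the true-negative rate. AUC is the
#' normalized Mann-Whitney statistic of the decision scores (ties count
#' one half), i.e. the probability that a random positive subject scores
#' above a random negative one.
#'
#' @param truth logical vector (`TRUE` = positive class) or factor whose
#'   second level is the positive class.
#' @param predicted predictions in the same encoding.
#' @param scores real decision values, higher = more patient-like.
#' @return Named numeric vector `c(ACC, SEN, SPE, AUC)`.
#' @examples
#' classification_metrics(c(TRUE, TRUE, FALSE, FALSE),
#'                        c(TRUE, FALSE, FALSE, FALSE),
#'                        scores = c(2, -1, -2, -3))
#' @export
classification_metrics <- function(truth, predicted, scores) {
  as_pos <- function(z) as.logical(if (is.factor(z)) z == levels(z)[2L] else z)
  truth <- as_pos(truth); predicted <- as_pos(predicted)
  stopifnot(length(truth) == length(predicted),
            length(truth) == length(scores))
  P <- sum(truth); N <- sum(!truth)
  if (P == 0L || N == 0L)
    stop("both classes must be present to compute sensitivity/AUC")
  tp <- sum(predicted & truth); tn <- sum(!predicted & !truth)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[truth]) - P * (P + 1) / 2) / (P * N)
  c(ACC = (tp + tn) / (P + N), SEN = tp / P, SPE = tn / N, AUC = auc)
}

# --- SVM on a precomputed kernel (kernlab), with stable score orientation

svm_train <- function(K, y, C = 1) {
  y <- factor(y)
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y,
                       type = "C-svc", C = C, scaled = FALSE, fit = FALSE)
  sv <- kernlab::SVindex(fit)
  alpha <- unlist(kernlab::coef(fit))
  b <- kernlab::b(fit)
  dec <- as.numeric(K[, sv, drop = FALSE] %*% alpha - b)
  # Decision values are computed directly from the dual coefficients;
  # kernlab's sign convention (which class the positive side means) is
  # checked once per fit on the most confident training row, and the
  # orientation fixed so that score > 0 <=> positive (second-level) class.
  orient <- 1
  i0 <- which.max(abs(dec))
  if (abs(dec[i0]) > 0) {
    lab0 <- as.character(kernlab::predict(
      fit, kernlab::as.kernelMatrix(K[i0, sv, drop = FALSE])))
    if ((dec[i0] > 0) != (lab0 == levels(y)[2L])) orient <- -1
  }
  list(sv = sv, alpha = alpha, b = b, orient = orient, levels = levels(y))
}

svm_predict <- function(model, Kcross) {
  scores <- model$orient *
    as.numeric(Kcross[, model$sv, drop = FALSE] %*% model$alpha - model$b)
  list(predicted = factor(model$levels[(scores > 0) + 1L],
                          levels = model$levels),
       scores = scores)
}
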