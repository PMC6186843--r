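# Repeated stratified k-fold cross-validation of the multikernel
# classifier, with all supervised steps (region selection, pattern mining,
# WL vocabulary, beta search) recomputed inside every training fold.

#' Evaluate the classifier under repeated stratified cross-validation
#'
#' The cohort is split into `folds` stratified parts; each part is held out
#' once while [mstmkl()] is fitted on the remainder and scores the held-out
#' subjects. The whole procedure is repeated `repetitions` times with fresh
#' random splits; reported metrics are the arithmetic means over
#' repetitions of the per-repetition pooled-prediction metrics. Fully
#' reproducible: repetition seeds are derived deterministically from
#' `seed`.
#'
#' @param cohort an [mst_cohort()].
#' @param folds number of outer folds; default 10.
#' @param repetitions number of repetitions; default 50.
#' @param seed master integer seed.
#' @param ... tuning parameters passed to [mstmkl()] (`support`,
#'   `threshold`, `h`, `alpha`, `beta`, `C`, `pattern_mode`, `method`, ...).
#' @return Object of class `mstmkl_cv`: list with `metrics` (mean ACC, SEN,
#'   SPE, AUC), `per_repetition` (data frame), `folds` (per-repetition,
#'   per-fold detail: test ids, truth, predictions, scores, chosen beta,
#'   selected regions, number of significant regions before fallback,
#'   selected-pattern count and edge keys), `config`, `seed`.
#' @export
mstmkl_cv <- function(cohort, folds = 10, repetitions = 50, seed = 1, ...) {
  stopifnot(inherits(cohort, "mst_cohort"))
  n <- length(cohort$ids)
  if (folds < 2L || folds > n) stop("folds must lie in [2, n]")
  dots <- list(...)
  pos_level <- levels(cohort$y)[2L]
  per_rep <- vector("list", repetitions)
  detail <- vector("list", repetitions)
  for (r in seq_len(repetitions)) {
    set.seed(seed + r)
    fold <- stratified_folds(cohort$y, folds)
    truth <- pred <- character(n)
    score <- numeric(n)
    fold_info <- vector("list", folds)
    for (f in seq_len(folds)) {
      tr <- which(fold != f)
      te <- which(fold == f)
      if (length(te) == 0L) next
      fit <- do.call(mstmkl, c(list(cohort = cohort[tr],
                                    seed = seed + 10000L + r * 100L + f),
                               dots))
      out <- predict(fit, cohort[te])
      truth[te] <- as.character(cohort$y[te])
      pred[te] <- as.character(out$predicted)
      score[te] <- out$score
      fold_info[[f]] <- list(
        fold = f,
        test_ids = cohort$ids[te],
        truth = as.character(cohort$y[te]),
        predicted = as.character(out$predicted),
        scores = out$score,
        beta = fit$beta,
        selected_regions = if (is.null(fit$selection)) integer(0)
                           else fit$selection$selected,
        n_significant = if (is.null(fit$n_significant)) NA_integer_
                        else fit$n_significant,
        n_patterns = if (is.null(fit$patterns)) NA_integer_
                     else length(fit$patterns),
        pattern_edges = if (is.null(fit$patterns)) character(0)
                        else sort(unique(unlist(
                          lapply(fit$patterns,
                                 function(p) edge_keys(p$edges))))))
    }
    m <- classification_metrics(truth == pos_level, pred == pos_level, score)
    per_rep[[r]] <- c(repetition = r, m)
    detail[[r]] <- fold_info
  }
  per_rep <- as.data.frame(do.call(rbind, per_rep))
  config <- c(list(folds = folds, repetitions = repetitions, seed = seed),
              dots)
  structure(list(metrics = colMeans(per_rep[, c("ACC", "SEN", "SPE", "AUC")]),
                 per_repetition = per_rep,
                 folds = detail,
                 config = config,
                 seed = seed,
                 ids = cohort$ids,
                 positive = cohort$positive),
            class = "mstmkl_cv")
}

#' @export
print.mstmkl_cv <- function(x, ...) {
  cat(sprintf(
    "<mstmkl_cv: %d x %d-fold CV, %d subjects (positive = %s)>\n",
    x$config$repetitions, x$config$folds, length(x$ids), x$positive))
  cat(sprintf("  ACC %.3f  SEN %.3f  SPE %.3f  AUC %.3f (means over %d reps)\n",
              x$metrics["ACC"], x$metrics["SEN"], x$metrics["SPE"],
              x$metrics["AUC"], x$config$repetitions))
  invisible(x)
}

#' @export
summary.mstmkl_cv <- function(object, ...) {
  print(object)
  sds <- apply(object$per_repetition[, c("ACC", "SEN", "SPE", "AUC")], 2, sd)
  cat("  per-repetition SD: ",
      paste(sprintf("%s %.3f", names(sds), sds), collapse = "  "), "\n")
  betas <- unlist(lapply(object$folds, function(rep_)
    vapply(rep_, function(f) f$beta, numeric(1))))
  cat("  chosen beta: ")
  print(table(betas))
  invisible(object)
}

# pooled (over repetitions) truth/score pairs for ROC construction
pooled_scores <- function(x) {
  truth <- unlist(lapply(x$folds, function(rep_)
    unlist(lapply(rep_, `[[`, "truth"))))
  scores <- unlist(lapply(x$folds, function(rep_)
    unlist(lapply(rep_, `[[`, "scores"))))
  list(truth = truth == x$positive, scores = scores)
}

#' ROC curve points from a cross-validation report
#'
#' @param x an `mstmkl_cv` object.
#' @return Data frame with columns `threshold`, `fpr`, `tpr` from the
#'   pooled decision scores.
#' @export
roc_points <- function(x) {
  stopifnot(inherits(x, "mstmkl_cv"))
  p <- pooled_scores(x)
  r <- pROC::roc(response = p$truth, predictor = p$scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  data.frame(threshold = r$thresholds, fpr = 1 - r$specificities,
             tpr = r$sensitivities)
}

#' Plot the pooled ROC curve of a cross-validation report
#'
#' @param x an `mstmkl_cv` object.
#' @param ... passed to [pROC::plot.roc()].
#' @export
plot.mstmkl_cv <- function(x, ...) {
  p <- pooled_scores(x)
  r <- pROC::roc(response = p$truth, predictor = p$scores,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  pROC::plot.roc(r, ...)
  invisible(r)
}
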