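# Readers and writers for the interchange formats, plus the top-level
# pipeline orchestration used by the command-line entry point.

split_fields <- function(line) {
  strsplit(trimws(line), "[,\t;]+|[[:space:]]+")[[1]]
}

#' Read a delimited ROI time-series file
#'
#' Accepts tab-, comma-, semicolon- or whitespace-delimited numeric text,
#' rows = time points, columns = regions. A non-numeric first row is
#' treated as a header and skipped.
#'
#' @param path file path.
#' @return T x R numeric matrix.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)
  first <- suppressWarnings(as.numeric(split_fields(lines[1L])))
  start <- if (anyNA(first)) 2L else 1L
  if (start > length(lines)) stop("no data rows in ", path)
  rows <- lapply(seq(start, length(lines)), function(i) {
    f <- split_fields(lines[i])
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop("non-numeric value in ", path, " at row ", i, ": ",
           paste(f[is.na(v)], collapse = ", "))
    v
  })
  nc <- lengths(rows)
  if (length(unique(nc)) != 1L)
    stop("ragged rows in ", path, ": row ",
         start - 1L + which(nc != nc[1L])[1L], " has ",
         nc[nc != nc[1L]][1L], " fields, expected ", nc[1L])
  do.call(rbind, rows)
}

#' Read a square symmetric correlation matrix from delimited text
#'
#' @param path file path.
#' @return Symmetric R x R matrix.
#' @export
read_corr_matrix <- function(path) {
  m <- read_timeseries(path)
  if (nrow(m) != ncol(m))
    stop("correlation matrix must be square, got ", nrow(m), " x ", ncol(m))
  if (max(abs(m - t(m))) > 1e-8)
    stop("correlation matrix is not symmetric: ", path)
  (m + t(m)) / 2
}

#' Read a cohort manifest and its subjects
#'
#' The manifest is a CSV with columns `subject_id`, `path`, `group`;
#' relative paths resolve against the manifest's directory. Exactly two
#' group tokens must occur, and the positive (patient) token must be named
#' explicitly -- sensitivity/specificity semantics depend on it.
#'
#' @param path manifest CSV path.
#' @param positive_label group token of the patient class.
#' @param input whether the per-subject files hold ROI time series
#'   (default) or precomputed symmetric correlation matrices.
#' @return List of [subject_record()] objects with data loaded.
#' @export
read_manifest <- function(path, positive_label,
                          input = c("timeseries", "corr")) {
  input <- match.arg(input)
  if (!file.exists(path)) stop("manifest not found: ", path)
  mf <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "group")
  if (!all(need %in% names(mf)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(mf$subject_id))
    stop("duplicate subject_id in manifest: ",
         paste(unique(mf$subject_id[duplicated(mf$subject_id)]),
               collapse = ", "))
  tokens <- sort(unique(mf$group))
  if (length(tokens) != 2L)
    stop("manifest must contain exactly 2 group tokens, found: ",
         paste(tokens, collapse = ", "))
  if (!positive_label %in% tokens)
    stop("positive_label '", positive_label, "' not among group tokens: ",
         paste(tokens, collapse = ", "))
  base <- dirname(normalizePath(path))
  lapply(seq_len(nrow(mf)), function(i) {
    p <- mf$path[i]
    if (!file.exists(p)) p <- file.path(base, mf$path[i])
    if (!file.exists(p))
      stop("data file for subject ", mf$subject_id[i],
           " not found: ", mf$path[i])
    if (input == "corr")
      subject_record(mf$subject_id[i], mf$group[i],
                     corr = read_corr_matrix(p))
    else
      subject_record(mf$subject_id[i], mf$group[i],
                     timeseries = read_timeseries(p))
  })
}

#' Write the per-subject betweenness table
#'
#' CSV with rows = subjects and columns = region labels.
#'
#' @param cohort an [mst_cohort()] (or a betweenness matrix with subject
#'   row names).
#' @param path output path.
#' @export
write_betweenness_table <- function(cohort, path) {
  B <- if (inherits(cohort, "mst_cohort")) cohort$B else as.matrix(cohort)
  df <- data.frame(subject_id = rownames(B), B, check.names = FALSE,
                   row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a weighted graph as an edge-list text file
#'
#' @param g a [labeled_graph()] (weights optional).
#' @param path output path.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "labeled_graph"))
  w <- if (is.null(g$weights)) rep(1, nrow(g$edges)) else g$weights
  lines <- c("label_i\tlabel_j\tweight",
             sprintf("%d\t%d\t%.17g", g$edges[, 1L], g$edges[, 2L], w))
  writeLines(lines, path)
  invisible(path)
}

#' Write a kernel matrix with subject-id header row and column
#'
#' @param K kernel matrix with subject ids as dimnames.
#' @param path output path.
#' @export
write_kernel_matrix <- function(K, path) {
  ids <- rownames(K)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(K)))
  lines <- c(paste(c("subject_id", ids), collapse = "\t"),
             vapply(seq_len(nrow(K)), function(i)
               paste(c(ids[i], sprintf("%.17g", K[i, ])), collapse = "\t"),
               ""))
  writeLines(lines, path)
  invisible(path)
}

#' Write scored patterns as JSON lines
#'
#' One JSON object per pattern: `edges`, `freq_pos`, `freq_neg`,
#' `freq_diff`, `source_group`.
#'
#' @param patterns list of scored `subgraph_pattern` objects.
#' @param path output path.
#' @export
write_patterns_jsonl <- function(patterns, path) {
  lines <- vapply(patterns, function(p)
    jsonlite::toJSON(list(
      edges = apply(p$edges, 1L, as.integer, simplify = FALSE),
      freq_pos = p$freq_pos, freq_neg = p$freq_neg,
      freq_diff = p$freq_diff, source_group = p$source_group),
      auto_unbox = TRUE, digits = NA), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write the region-selection report
#'
#' CSV with one row per region: label, t-test p-value, selected flag.
#'
#' @param sel a [select_regions()] result.
#' @param path output path.
#' @export
write_selection_table <- function(sel, path) {
  stopifnot(inherits(sel, "region_selection"))
  labels <- as.integer(names(sel$pvalues))
  utils::write.csv(data.frame(
    region = labels,
    p_value = unname(sel$pvalues),
    selected = labels %in% sel$selected),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = NA)), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a cross-validation report as JSON
#'
#' The effective configuration, its MD5 hash and the master seed are
#' embedded so artifacts are traceable and re-runnable.
#'
#' @param cv an `mstmkl_cv` object.
#' @param path output path.
#' @export
write_cv_report <- function(cv, path) {
  stopifnot(inherits(cv, "mstmkl_cv"))
  obj <- list(
    config = cv$config,
    config_hash = config_hash(cv$config),
    seed = cv$seed,
    positive = cv$positive,
    metrics = as.list(cv$metrics),
    per_repetition = cv$per_repetition,
    folds = cv$folds)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full classification pipeline on a cohort manifest
#'
#' Orchestrates tree construction, repeated cross-validation, and artifact
#' writing: `report.json` (metrics + per-fold detail + config echo/hash),
#' `roc.csv` (pooled ROC points), `betweenness.csv`, and -- from a final
#' fit on all subjects -- `selection.csv`, `patterns.jsonl`,
#' `kernel_linear.tsv`, `kernel_graph.tsv`.
#'
#' @param manifest manifest CSV path, or an [mst_cohort()] directly.
#' @param positive_label patient-class token (required with a manifest
#'   path).
#' @param out_dir directory for artifacts (created); `NULL` writes nothing.
#' @param folds,repetitions,seed cross-validation protocol.
#' @param ... tuning parameters passed to [mstmkl()].
#' @return The `mstmkl_cv` report, invisibly if `out_dir` is set.
#' @export
run_pipeline <- function(manifest, positive_label = NULL, out_dir = NULL,
                         folds = 10, repetitions = 50, seed = 1, ...) {
  t0 <- Sys.time()
  cohort <- if (inherits(manifest, "mst_cohort")) manifest
  else {
    if (is.null(positive_label))
      stop("positive_label is required when reading a manifest")
    mst_cohort(read_manifest(manifest, positive_label), positive_label)
  }
  message(sprintf("[connectivity] %d subjects, %d regions (%.1fs)",
                  length(cohort$ids), cohort$R,
                  as.numeric(Sys.time() - t0, units = "secs")))
  t1 <- Sys.time()
  cv <- mstmkl_cv(cohort, folds = folds, repetitions = repetitions,
                  seed = seed, ...)
  message(sprintf("[cv] %d x %d-fold done (%.1fs): ACC %.3f AUC %.3f",
                  repetitions, folds,
                  as.numeric(Sys.time() - t1, units = "secs"),
                  cv$metrics["ACC"], cv$metrics["AUC"]))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cv_report(cv, file.path(out_dir, "report.json"))
    utils::write.csv(roc_points(cv), file.path(out_dir, "roc.csv"),
                     row.names = FALSE, quote = FALSE)
    write_betweenness_table(cohort, file.path(out_dir, "betweenness.csv"))
    fit <- mstmkl(cohort, seed = seed, ...)
    if (!is.null(fit$selection))
      write_selection_table(fit$selection,
                            file.path(out_dir, "selection.csv"))
    if (!is.null(fit$patterns))
      write_patterns_jsonl(fit$patterns,
                           file.path(out_dir, "patterns.jsonl"))
    ids <- cohort$ids
    if (!is.null(fit$X))
      write_kernel_matrix(
        normalize_kernel(structure(tcrossprod(fit$X),
                                   dimnames = list(ids, ids))),
        file.path(out_dir, "kernel_linear.tsv"))
    if (!is.null(fit$wl_train))
      write_kernel_matrix(
        normalize_kernel(structure(
          as.matrix(Matrix::tcrossprod(fit$wl_train$features)),
          dimnames = list(ids, ids))),
        file.path(out_dir, "kernel_graph.tsv"))
    message("[artifacts] written to ", out_dir)
    return(invisible(cv))
  }
  cv
}
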