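# Synthetic two-group cohorts of ROI time series with planted, recoverable
# effects: a hub whose connections strengthen in the patient group (a
# betweenness effect) and a connected motif of elevated correlations (a
# subgraph effect). Planting operates on the population correlation
# (signal) level, never by editing sampled series, so Pearson/MST behaviour
# downstream stays statistically honest.

#' Specification of a synthetic two-group cohort
#'
#' Builds the latent structure once, deterministically from `seed`: a
#' random connected backbone graph with edge correlations drawn uniformly
#' from \[0.2, 0.45\] (weak-to-moderate functional coupling), hub regions
#' (the highest-degree backbone nodes unless given), and a connected motif
#' (a path over regions disjoint from the hubs unless given).
#'
#' @param R region count; default 90.
#' @param T_len time points per subject; default 130.
#' @param n_pos,n_neg subjects in the patient / control group; defaults
#'   32 / 28.
#' @param base_density backbone connection probability; default 0.15.
#' @param n_hubs number of hub regions; default 2.
#' @param hub_effect correlation added to all of a hub's connections in the
#'   patient group (>= 0); default 0.35.
#' @param motif_size nodes in the planted motif path; default 4.
#' @param motif_effect correlation added to motif edges in the patient
#'   group (>= 0); default 0.8, strong enough that motif edges dominate
#'   every alternative tree path after positive-definite repair.
#' @param noise_sd observation noise standard deviation (> 0); default 0.2.
#' @param seed integer seed fixing backbone, weights, hubs, motif and the
#'   sampled series.
#' @param hubs,motif optional explicit hub labels / motif edge matrix.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(R = 90, T_len = 130, n_pos = 32, n_neg = 28,
                       base_density = 0.15, n_hubs = 2, hub_effect = 0.35,
                       motif_size = 4, motif_effect = 0.8, noise_sd = 0.2,
                       seed = 1, hubs = NULL, motif = NULL) {
  stopifnot(R >= 5, T_len >= 3, n_pos >= 1, n_neg >= 1,
            base_density > 0, base_density <= 1,
            hub_effect >= 0, motif_effect >= 0, noise_sd > 0,
            motif_size >= 2, motif_size <= R)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  # connected backbone: random recursive tree + Erdos-Renyi extra edges
  edges <- cbind(2:R, vapply(2:R, function(k) sample.int(k - 1L, 1L), 1L))
  pairs <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  extra <- pairs[stats::runif(nrow(pairs)) < base_density, , drop = FALSE]
  backbone <- keys_to_edges(unique(edge_keys(rbind(edges, extra))))
  weights <- stats::runif(nrow(backbone), 0.2, 0.45)
  deg <- tabulate(as.vector(backbone), nbins = R)
  if (is.null(hubs)) hubs <- order(-deg, seq_len(R))[seq_len(n_hubs)]
  hubs <- sort(as.integer(hubs))
  if (is.null(motif)) {
    cand <- setdiff(seq_len(R), hubs)
    vs <- sample(cand, motif_size)
    motif <- cbind(vs[-length(vs)], vs[-1L])
  }
  motif <- keys_to_edges(edge_keys(as.matrix(motif)))
  structure(list(R = R, T_len = T_len, n_pos = n_pos, n_neg = n_neg,
                 base_density = base_density, hub_effect = hub_effect,
                 motif_effect = motif_effect, noise_sd = noise_sd,
                 seed = seed, backbone = backbone, weights = weights,
                 hubs = hubs, motif = motif),
            class = "synth_spec")
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<synth_spec: R = %d, T = %d, %d/%d subjects, %d backbone edges,\n",
    "  hubs {%s} effect %.2f, motif {%s} effect %.2f, noise sd %.2f, ",
    "seed %d>\n"),
    x$R, x$T_len, x$n_pos, x$n_neg, nrow(x$backbone),
    paste(x$hubs, collapse = ","), x$hub_effect,
    paste(edge_keys(x$motif), collapse = " "), x$motif_effect,
    x$noise_sd, x$seed))
  invisible(x)
}

#' Population correlation matrix of one synthetic group
#'
#' The shared backbone correlations define both groups; the patient
#' (positive) group additionally gains `hub_effect` on every hub
#' row/column and `motif_effect` on motif edges (entries capped at 0.95).
#' The target is projected to the nearest positive-definite matrix by
#' eigenvalue clipping (minimum eigenvalue 1e-6) and rescaled to unit
#' diagonal. If the repair reorders the motif below background
#' correlations, an error advises smaller effects.
#'
#' @param spec a [synth_spec()].
#' @param group `"positive"` or `"negative"`.
#' @return R x R unit-diagonal positive-definite correlation matrix.
#' @export
build_group_covariance <- function(spec, group = c("positive", "negative")) {
  group <- match.arg(group)
  R <- spec$R
  A <- diag(1, R)
  for (k in seq_len(nrow(spec$backbone))) {
    i <- spec$backbone[k, 1L]; j <- spec$backbone[k, 2L]
    A[i, j] <- A[j, i] <- spec$weights[k]
  }
  if (group == "positive") {
    for (hb in spec$hubs) {
      A[hb, -hb] <- pmin(A[hb, -hb] + spec$hub_effect, 0.95)
      A[-hb, hb] <- A[hb, -hb]
    }
    for (k in seq_len(nrow(spec$motif))) {
      i <- spec$motif[k, 1L]; j <- spec$motif[k, 2L]
      A[i, j] <- A[j, i] <- min(A[i, j] + spec$motif_effect, 0.95)
    }
  }
  # eigenvalue clipping and unit-diagonal rescaling, iterated because the
  # rescale can push the smallest eigenvalue slightly back below the floor
  S <- A
  for (it in 1:50) {
    eg <- eigen(S, symmetric = TRUE)
    if (min(eg$values) >= 1e-6) break
    S <- eg$vectors %*% (pmax(eg$values, 1.05e-6) * t(eg$vectors))
    S <- stats::cov2cor(S)
    S <- (S + t(S)) / 2
    diag(S) <- 1
  }
  if (group == "positive" && spec$motif_effect > 0 &&
      !motif_ordering_ok(S, spec))
    stop("positive-definite repair distorted the motif ordering; ",
         "use smaller hub_effect/motif_effect")
  S
}

# motif edges must still dominate the background (non-backbone, non-hub,
# non-motif) correlations after repair, or the planted subgraph effect has
# been destroyed
motif_ordering_ok <- function(S, spec) {
  motif_vals <- S[spec$motif]
  bg <- upper.tri(S)
  bg[spec$backbone] <- FALSE
  bg[spec$backbone[, 2:1, drop = FALSE]] <- FALSE
  bg[spec$motif] <- FALSE
  bg[spec$motif[, 2:1, drop = FALSE]] <- FALSE
  bg[spec$hubs, ] <- FALSE
  bg[, spec$hubs] <- FALSE
  !any(bg) || min(motif_vals) > max(S[bg])
}

#' Generate a synthetic cohort of subject records
#'
#' Each subject's series is T independent draws from a zero-mean
#' multivariate normal with the group's correlation matrix, plus white
#' observation noise of standard deviation `noise_sd`. Deterministic given
#' the spec's seed.
#'
#' @param spec a [synth_spec()].
#' @return Object of class `synthetic_cohort`: list with `records` (list of
#'   [subject_record()], groups `"patient"` / `"control"`), `truth` (hub
#'   labels and motif edge matrix), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed + 1L)
  Lp <- chol(build_group_covariance(spec, "positive"))
  Ln <- chol(build_group_covariance(spec, "negative"))
  draw <- function(L) {
    Z <- matrix(stats::rnorm(spec$T_len * spec$R), spec$T_len, spec$R)
    Z %*% L + spec$noise_sd * matrix(stats::rnorm(spec$T_len * spec$R),
                                     spec$T_len, spec$R)
  }
  records <- vector("list", spec$n_pos + spec$n_neg)
  for (i in seq_len(spec$n_pos))
    records[[i]] <- subject_record(sprintf("P%03d", i), "patient",
                                   timeseries = draw(Lp))
  for (i in seq_len(spec$n_neg))
    records[[spec$n_pos + i]] <- subject_record(sprintf("C%03d", i),
                                                "control",
                                                timeseries = draw(Ln))
  structure(list(records = records,
                 truth = list(hubs = spec$hubs, motif = spec$motif),
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d patients + %d controls, R = %d, T = %d>\n",
              x$spec$n_pos, x$spec$n_neg, x$spec$R, x$spec$T_len))
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline's input format
#'
#' Writes one tab-delimited time-series file per subject (rows = time
#' points, columns = regions, full float precision for byte-exact
#' round-trips), a `manifest.csv` (subject_id, path, group) and
#' `ground_truth.json` (hubs, motif edges, seed).
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(cohort$records, function(r) {
    p <- file.path(dir, paste0(r$subject_id, ".tsv"))
    writeLines(apply(r$timeseries, 1L, function(row)
      paste(sprintf("%.17g", row), collapse = "\t")), p)
    p
  }, "")
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(
    subject_id = vapply(cohort$records, function(r) r$subject_id, ""),
    path = basename(paths),
    group = vapply(cohort$records, function(r) r$group, "")),
    manifest, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(hubs = cohort$truth$hubs,
         motif = apply(cohort$truth$motif, 1L, function(e) as.integer(e),
                       simplify = FALSE),
         seed = cohort$spec$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(manifest)
}
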