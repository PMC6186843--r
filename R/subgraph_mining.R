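# Frequent-subgraph mining over uniquely labeled graphs, frequency-
# difference scoring, discriminative-pattern selection, and network
# reconstruction.
#
# Because node labels are unique per graph (ROI identity), a pattern's
# occurrence in a host graph is exact edge-set containment; the miner grows
# patterns level-wise over frequent labeled edges (Apriori-style, the gSpan
# semantics specialized to this setting) with anti-monotone pruning.

new_pattern <- function(edges, freq, support_count = NA_integer_,
                        source_group = NA_character_) {
  edges <- keys_to_edges(edge_keys(edges))
  structure(list(edges = edges,
                 nodes = sort(unique(as.vector(edges))),
                 freq = freq,
                 support_count = support_count,
                 source_group = source_group,
                 freq_pos = NA_real_, freq_neg = NA_real_,
                 freq_diff = NA_real_),
            class = "subgraph_pattern")
}

#' @export
print.subgraph_pattern <- function(x, ...) {
  cat(sprintf(
    "<subgraph_pattern: %d edges {%s}; freq %.3f%s>\n",
    nrow(x$edges), paste(edge_keys(x$edges), collapse = " "), x$freq,
    if (is.na(x$freq_diff)) ""
    else sprintf("; pos %.3f neg %.3f diff %.3f", x$freq_pos, x$freq_neg,
                 x$freq_diff)))
  invisible(x)
}

pattern_key <- function(p) paste(edge_keys(p$edges), collapse = "|")

pattern_graph <- function(p) labeled_graph(p$nodes, p$edges)

#' Mine frequent connected subgraphs from a set of labeled graphs
#'
#' Finds connected subgraphs (>= 1 edge) occurring in at least a fraction
#' `s` of the graphs. Frequency of a pattern is the share of graphs that
#' contain all of its edges. In `"maximal"` mode (default) only patterns
#' with no frequent connected one-edge extension are returned -- by
#' anti-monotonicity this equals "no frequent proper super-pattern exists".
#' `"all"` mode returns every frequent pattern.
#'
#' @param graphs nonempty list of [labeled_graph()] objects in a shared
#'   label space.
#' @param s minimum frequency (support) in (0, 1]; a pattern is frequent
#'   when its frequency is at least `s`.
#' @param mode `"maximal"` or `"all"`.
#' @param source_group optional tag recorded on each pattern.
#' @param max_patterns safety bound on the number of frequent patterns
#'   explored; exceeded -> error advising a higher `s`.
#' @return List of `subgraph_pattern` objects, ordered by edge count then
#'   edge keys; each carries `freq` with respect to `graphs` only.
#' @export
mine_frequent_subgraphs <- function(graphs, s, mode = c("maximal", "all"),
                                    source_group = NA_character_,
                                    max_patterns = 1e5) {
  mode <- match.arg(mode)
  if (length(graphs) == 0L) stop("empty graph list")
  if (!is.numeric(s) || length(s) != 1L || s <= 0 || s > 1)
    stop("support s must lie in (0, 1], got ", s)
  n <- length(graphs)
  min_count <- ceiling(s * n - 1e-9)
  key_list <- lapply(graphs, edge_keys)
  all_keys <- sort(unique(unlist(key_list)))
  if (length(all_keys) == 0L) return(list())
  # incidence: edge x graph
  M <- vapply(key_list, function(k) all_keys %in% k, logical(length(all_keys)))
  M <- matrix(M, nrow = length(all_keys))
  cnt <- rowSums(M)
  fe <- which(cnt >= min_count)
  if (length(fe) == 0L) return(list())
  fedges <- keys_to_edges(all_keys[fe])
  fsupp <- M[fe, , drop = FALSE]
  nf <- nrow(fedges)
  # node -> incident frequent-edge indices
  node_ids <- sort(unique(as.vector(fedges)))
  inc <- lapply(node_ids, function(v)
    which(fedges[, 1L] == v | fedges[, 2L] == v))
  names(inc) <- node_ids
  edge_nodes <- lapply(seq_len(nf), function(k) fedges[k, ])

  seen <- new.env(parent = emptyenv(), hash = TRUE)
  results <- vector("list", 0L)
  n_found <- 0L

  frontier <- lapply(seq_len(nf), function(k)
    list(e = k, supp = fsupp[k, ], cnt = cnt[fe[k]],
         nodes = edge_nodes[[k]], maximal = TRUE))
  for (p in frontier) assign(paste(p$e, collapse = ","), TRUE, envir = seen)

  while (length(frontier) > 0L) {
    nxt <- vector("list", 0L)
    for (p in frontier) {
      cand <- setdiff(unique(unlist(inc[as.character(p$nodes)])), p$e)
      is_max <- TRUE
      for (ce in cand) {
        supp2 <- p$supp & fsupp[ce, ]
        c2 <- sum(supp2)
        if (c2 >= min_count) {
          is_max <- FALSE
          e2 <- sort(c(p$e, ce))
          k2 <- paste(e2, collapse = ",")
          if (!exists(k2, envir = seen, inherits = FALSE)) {
            assign(k2, TRUE, envir = seen)
            nxt[[length(nxt) + 1L]] <- list(
              e = e2, supp = supp2, cnt = c2,
              nodes = sort(unique(c(p$nodes, edge_nodes[[ce]]))),
              maximal = TRUE)
          }
        }
      }
      if (mode == "all" || is_max) {
        n_found <- n_found + 1L
        if (n_found > max_patterns)
          stop("more than ", max_patterns, " frequent patterns; raise the ",
               "support s or use maximal mode")
        results[[n_found]] <- new_pattern(
          fedges[p$e, , drop = FALSE], freq = p$cnt / n,
          support_count = p$cnt, source_group = source_group)
      }
    }
    if (n_found + length(nxt) > max_patterns)
      stop("more than ", max_patterns, " frequent patterns; raise the ",
           "support s or use maximal mode")
    frontier <- nxt
  }
  ord <- order(vapply(results, function(p) nrow(p$edges), 1L),
               vapply(results, pattern_key, ""))
  results[ord]
}

#' Frequency of a pattern within a graph set
#'
#' Share of graphs in `graphs` that contain every edge of `pattern`.
#'
#' @param pattern a `subgraph_pattern` or [labeled_graph()].
#' @param graphs nonempty list of [labeled_graph()] objects.
#' @return Frequency in \[0, 1\] (a rational with denominator
#'   `length(graphs)`).
#' @export
pattern_frequency <- function(pattern, graphs) {
  if (length(graphs) == 0L) stop("empty graph set")
  pg <- if (inherits(pattern, "subgraph_pattern")) pattern_graph(pattern)
        else pattern
  mean(vapply(graphs, contains_subgraph, logical(1), pattern = pg))
}

#' Frequency difference of a pattern between two groups
#'
#' The absolute difference of the pattern's frequencies in the positive and
#' negative graph sets; large values mark group-discriminative topology.
#'
#' @param pattern a `subgraph_pattern` or [labeled_graph()].
#' @param pos_graphs,neg_graphs nonempty lists of [labeled_graph()] objects.
#' @return Value in \[0, 1\].
#' @export
frequency_difference <- function(pattern, pos_graphs, neg_graphs) {
  abs(pattern_frequency(pattern, pos_graphs) -
        pattern_frequency(pattern, neg_graphs))
}

#' Score patterns against both groups and merge duplicates
#'
#' Deduplicates patterns by edge set (patterns mined independently from the
#' two groups often coincide) and fills `freq_pos`, `freq_neg` and
#' `freq_diff` by containment counts over the supplied graph sets.
#'
#' @param patterns list of `subgraph_pattern` objects.
#' @param pos_graphs,neg_graphs nonempty lists of [labeled_graph()] objects.
#' @return Deduplicated, scored list of patterns.
#' @export
score_patterns <- function(patterns, pos_graphs, neg_graphs) {
  if (length(pos_graphs) == 0L || length(neg_graphs) == 0L)
    stop("both graph sets must be nonempty")
  if (length(patterns) == 0L) return(list())
  keys <- vapply(patterns, pattern_key, "")
  keep <- !duplicated(keys)
  patterns <- patterns[keep]
  lapply(patterns, function(p) {
    pg <- pattern_graph(p)
    p$freq_pos <- pattern_frequency(pg, pos_graphs)
    p$freq_neg <- pattern_frequency(pg, neg_graphs)
    p$freq_diff <- abs(p$freq_pos - p$freq_neg)
    p
  })
}

#' Select discriminative patterns by frequency-difference threshold
#'
#' Keeps scored patterns whose frequency difference strictly exceeds `T`
#' (the threshold; default 0.13). An empty result is allowed and logged;
#' downstream reconstructions are then edgeless.
#'
#' @param patterns list of scored `subgraph_pattern` objects (see
#'   [score_patterns()]).
#' @param threshold nonnegative frequency-difference threshold.
#' @return Sub-list of `patterns`, deduplicated by edge set.
#' @export
select_discriminative <- function(patterns, threshold = 0.13) {
  if (threshold < 0) stop("threshold must be >= 0")
  if (length(patterns) == 0L) return(list())
  d <- vapply(patterns, function(p) p$freq_diff, numeric(1))
  if (anyNA(d)) stop("patterns must be scored first (see score_patterns)")
  out <- patterns[d > threshold]
  out[!duplicated(vapply(out, pattern_key, ""))]
}

#' Reconstruct networks from discriminative subgraphs
#'
#' For each subject's tree, deletes every edge that does not appear in any
#' selected discriminative pattern; all R nodes are retained (possibly
#' isolated), preserving only the group-discriminative topology.
#'
#' @param msts list of `mst_network` (or [labeled_graph()]) objects.
#' @param selected list of `subgraph_pattern` objects (may be empty; all
#'   reconstructions are then edgeless).
#' @return List of [labeled_graph()] objects aligned with `msts`.
#' @export
reconstruct_networks <- function(msts, selected) {
  allowed <- unique(unlist(lapply(selected, function(p) edge_keys(p$edges))))
  lapply(msts, function(g) {
    keys <- edge_keys(g)
    keep <- keys %in% allowed
    labeled_graph(g$nodes, g$edges[keep, , drop = FALSE])
  })
}
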