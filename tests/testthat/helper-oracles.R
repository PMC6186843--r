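# Independent oracles and random-instance generators used across the test
# suite. Every oracle is written against first principles (enumeration,
# textbook formulas, string expansion) and shares no code with the package
# implementation it checks.

# ---- random instances -------------------------------------------------

# random labeled tree on n nodes (random attachment), uniform weights
random_tree <- function(n, labels = seq_len(n), weighted = FALSE) {
  edges <- if (n >= 2)
    cbind(labels[2:n],
          labels[vapply(2:n, function(k) sample.int(k - 1L, 1L), 1L)])
  else NULL
  labeled_graph(labels, edges,
                weights = if (weighted && n >= 2) runif(n - 1L) else NULL)
}

# random connected weighted graph with distinct weights
random_connected_graph <- function(n, extra_p = 0.4) {
  base <- random_tree(n)
  pairs <- t(combn(n, 2L))
  keys <- paste(pairs[, 1], pairs[, 2], sep = "-")
  have <- keys %in% mstmkl:::edge_keys(base)
  add <- runif(nrow(pairs)) < extra_p & !have
  edges <- rbind(base$edges, pairs[add, , drop = FALSE])
  w <- sample(seq_len(nrow(edges))) + runif(nrow(edges), 0, 0.4)  # distinct
  labeled_graph(seq_len(n), edges, weights = w)
}

# ---- spanning trees ---------------------------------------------------

# exhaustive maximum-spanning-tree search by enumerating all (n-1)-edge
# subsets and keeping acyclic spanning ones
oracle_max_spanning_tree <- function(g) {
  n <- length(g$nodes)
  m <- nrow(g$edges)
  stopifnot(m >= n - 1)
  best_w <- -Inf
  best_keys <- NULL
  for (sel in asplit(combn(m, n - 1L), 2L)) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (k in sel) {
      a <- find(match(g$edges[k, 1L], g$nodes))
      b <- find(match(g$edges[k, 2L], g$nodes))
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) {
      w <- sum(g$weights[sel])
      if (w > best_w) {
        best_w <- w
        best_keys <- sort(mstmkl:::edge_keys(g$edges[sel, , drop = FALSE]))
      }
    }
  }
  list(weight = best_w, keys = best_keys)
}

# ---- betweenness ------------------------------------------------------

# all-pairs path-walk betweenness: for every ordered pair walk the unique
# tree path and count interior visits
oracle_betweenness <- function(tree) {
  n <- length(tree$nodes)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(tree$edges))) {
    a <- match(tree$edges[k, 1L], tree$nodes)
    b <- match(tree$edges[k, 2L], tree$nodes)
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  path_between <- function(h, j) {
    # BFS from h recording parents, then walk back from j
    parent <- rep(NA_integer_, n)
    parent[h] <- h
    q <- h
    while (length(q)) {
      v <- q[1L]; q <- q[-1L]
      for (u in adj[[v]]) if (is.na(parent[u])) { parent[u] <- v; q <- c(q, u) }
    }
    p <- j
    path <- j
    while (p != h) { p <- parent[p]; path <- c(path, p) }
    path
  }
  counts <- numeric(n)
  for (h in seq_len(n)) for (j in seq_len(n)) {
    if (h == j) next
    interior <- setdiff(path_between(h, j), c(h, j))
    counts[interior] <- counts[interior] + 1
  }
  stats::setNames(counts / ((n - 1) * (n - 2)), tree$nodes)
}

# ---- subgraph mining --------------------------------------------------

# connected edge-induced subgraphs of one graph, as sorted key vectors
oracle_connected_subsets <- function(g) {
  m <- nrow(g$edges)
  keys <- mstmkl:::edge_keys(g)
  out <- list()
  for (size in seq_len(m)) {
    for (sel in asplit(combn(m, size), 2L)) {
      sub <- g$edges[sel, , drop = FALSE]
      nodes <- unique(as.vector(sub))
      parent <- seq_along(nodes)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (k in seq_len(nrow(sub))) {
        a <- find(match(sub[k, 1L], nodes)); b <- find(match(sub[k, 2L], nodes))
        if (a != b) parent[a] <- b
      }
      if (length(unique(vapply(seq_along(nodes), find, 1L))) == 1L)
        out[[length(out) + 1L]] <- sort(keys[sel])
    }
  }
  out
}

# brute-force frequent mining: enumerate every connected subgraph occurring
# anywhere in the cohort, count containment, filter by frequency
oracle_frequent_subgraphs <- function(graphs, s) {
  key_sets <- lapply(graphs, mstmkl:::edge_keys)
  cand <- unique(unlist(lapply(graphs, function(g)
    vapply(oracle_connected_subsets(g), paste, "", collapse = "|")),
    use.names = FALSE))
  freq <- vapply(cand, function(ck) {
    ks <- strsplit(ck, "|", fixed = TRUE)[[1]]
    mean(vapply(key_sets, function(h) all(ks %in% h), TRUE))
  }, 1)
  sort(names(freq)[freq >= s - 1e-9])
}

# generic label-preserving subgraph isomorphism that does not exploit the
# uniqueness shortcut: tries every label-compatible node mapping
oracle_subgraph_iso <- function(host, pattern) {
  maps <- lapply(pattern$nodes, function(v) which(host$nodes == v))
  if (any(lengths(maps) == 0L)) return(FALSE)
  grid <- expand.grid(maps)
  hk <- mstmkl:::edge_keys(host)
  for (r in seq_len(nrow(grid))) {
    img <- host$nodes[as.integer(grid[r, ])]
    if (anyDuplicated(img)) next
    lut <- stats::setNames(img, pattern$nodes)
    pe <- pattern$edges
    mapped <- cbind(lut[as.character(pe[, 1L])], lut[as.character(pe[, 2L])])
    if (all(mstmkl:::edge_keys(mapped) %in% hk)) return(TRUE)
  }
  FALSE
}

# ---- Weisfeiler-Lehman ------------------------------------------------

# WL kernel via uncompressed string labels: no dictionary, labels are the
# fully expanded neighbourhood strings; K[i,j] = sum over shared strings of
# count products
oracle_wl_kernel <- function(graphs, h) {
  feats <- lapply(graphs, function(g) {
    nv <- length(g$nodes)
    adj <- lapply(seq_len(nv), function(i) integer(0))
    for (k in seq_len(nrow(g$edges))) {
      a <- match(g$edges[k, 1L], g$nodes)
      b <- match(g$edges[k, 2L], g$nodes)
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    lab <- as.character(lengths(adj))
    all_feats <- paste0("0:", lab)
    if (h >= 1) for (it in seq_len(h)) {
      lab <- vapply(seq_len(nv), function(v)
        paste0(lab[v], "(", paste(sort(lab[adj[[v]]]), collapse = ";"), ")"),
        "")
      all_feats <- c(all_feats, paste0(it, ":", lab))
    }
    table(all_feats)
  })
  n <- length(graphs)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(names(feats[[i]]), names(feats[[j]]))
    K[i, j] <- sum(as.numeric(feats[[i]][shared]) *
                     as.numeric(feats[[j]][shared]))
  }
  K
}

# ---- statistics -------------------------------------------------------

# pooled-variance two-sample t-test p-value from the textbook formula
oracle_t_pvalue <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * stats::pt(-abs(tstat), df = nx + ny - 2)
}

# AUC by brute-force pair counting (ties count one half)
oracle_auc <- function(truth, scores) {
  pos <- scores[truth]; neg <- scores[!truth]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# small helper: quick synthetic cohort for pipeline tests
tiny_cohort <- function(R = 20, T_len = 130, n = 10, seed = 5, ...) {
  spec <- synth_spec(R = R, T_len = T_len, n_pos = n, n_neg = n,
                     seed = seed, ...)
  mst_cohort(generate_cohort(spec)$records, "patient")
}
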