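p5 <- labeled_graph(1:5, cbind(1:4, 2:5))

test_that("identical-tree cohort at s = 1 yields every connected subtree", {
  pats <- mine_frequent_subgraphs(list(p5, p5, p5), s = 1, mode = "all")
  expect_length(pats, 10L)  # sub-paths of P5 with >= 1 edge
  expect_true(all(vapply(pats, function(p) p$freq, 1) == 1))
  # maximal mode collapses them to the full path
  mx <- mine_frequent_subgraphs(list(p5, p5, p5), s = 1, mode = "maximal")
  expect_length(mx, 1L)
  expect_equal(mstmkl:::edge_keys(mx[[1]]$edges), mstmkl:::edge_keys(p5))
})

test_that("frequency is the containment share; support bounds enforced", {
  g2 <- labeled_graph(1:5, rbind(c(1, 2), c(2, 3)))
  g3 <- labeled_graph(1:5, rbind(c(4, 5)))
  pats <- mine_frequent_subgraphs(list(p5, g2, g3), s = 0.6, mode = "all")
  k12 <- vapply(pats, function(p)
    identical(mstmkl:::edge_keys(p$edges), "1-2"), TRUE)
  expect_equal(pats[[which(k12)]]$freq, 2 / 3)
  # a pattern present in 2 of 3 graphs is frequent iff s <= 2/3
  expect_false(any(vapply(
    mine_frequent_subgraphs(list(p5, g2, g3), s = 0.7, mode = "all"),
    function(p) identical(mstmkl:::edge_keys(p$edges), "1-2"), TRUE)))
  expect_error(mine_frequent_subgraphs(list(p5), s = 1.001), "\\(0, 1\\]")
  expect_error(mine_frequent_subgraphs(list(p5), s = 0), "\\(0, 1\\]")
  expect_error(mine_frequent_subgraphs(list(), s = 0.5), "empty")
})

test_that("miner (all mode) equals brute-force enumeration", {
  set.seed(31)
  for (rep in 1:12) {
    cohort <- lapply(seq_len(sample(3:5, 1)), function(i) {
      n <- sample(4:8, 1)
      random_tree(n, labels = sample(10, n))
    })
    for (s in c(0.5, 0.7, 1.0)) {
      mined <- mine_frequent_subgraphs(cohort, s = s, mode = "all")
      keys <- sort(vapply(mined, mstmkl:::pattern_key, ""))
      expect_identical(keys, oracle_frequent_subgraphs(cohort, s))
      # frequencies are rationals over |G| and anti-monotone
      n <- length(cohort)
      for (p in mined) {
        expect_equal(p$freq, p$support_count / n)
        expect_equal(p$freq, pattern_frequency(p, cohort))
        if (nrow(p$edges) > 1) {
          for (k in seq_len(nrow(p$edges))) {
            sub <- p$edges[-k, , drop = FALSE]
            subg <- labeled_graph(unique(as.vector(sub)), sub)
            if (mstmkl:::is_connected_graph(subg))
              expect_gte(pattern_frequency(subg, cohort), p$freq)
          }
        }
      }
    }
  }
})

test_that("mining is invariant to graph order and patterns from trees are trees", {
  set.seed(32)
  cohort <- lapply(1:4, function(i) random_tree(7))
  a <- mine_frequent_subgraphs(cohort, 0.5, mode = "all")
  b <- mine_frequent_subgraphs(rev(cohort), 0.5, mode = "all")
  expect_identical(vapply(a, mstmkl:::pattern_key, ""),
                   vapply(b, mstmkl:::pattern_key, ""))
  expect_identical(vapply(a, function(p) p$freq, 1),
                   vapply(b, function(p) p$freq, 1))
  for (p in a)
    expect_equal(nrow(p$edges), length(p$nodes) - 1L)
})

test_that("frequency differences follow the two-group definition", {
  pos <- list(p5, labeled_graph(1:5, rbind(c(1, 2))),
              labeled_graph(1:5, rbind(c(1, 2), c(2, 3))),
              labeled_graph(1:5, rbind(c(4, 5))))
  neg <- list(labeled_graph(1:5, rbind(c(1, 2))),
              labeled_graph(1:5, rbind(c(4, 5))),
              labeled_graph(1:5, rbind(c(3, 4))),
              labeled_graph(1:5, rbind(c(2, 3))))
  e12 <- labeled_graph(1:2, rbind(c(1, 2)))
  # pattern in 3/4 positives and 1/4 negatives
  expect_equal(pattern_frequency(e12, pos), 3 / 4)
  expect_equal(pattern_frequency(e12, neg), 1 / 4)
  expect_equal(frequency_difference(e12, pos, neg), 0.5)
  # everywhere -> difference 0
  allg <- list(p5, p5)
  expect_equal(frequency_difference(e12, allg, allg), 0)
  expect_error(pattern_frequency(e12, list()), "empty")
})

test_that("scoring fills both frequencies and |pos - neg|", {
  pos <- list(p5, p5, p5)
  neg <- list(labeled_graph(1:5, rbind(c(1, 2))),
              labeled_graph(1:5, rbind(c(4, 5))))
  pats <- mine_frequent_subgraphs(pos, 1, mode = "all")
  scored <- score_patterns(pats, pos, neg)
  for (p in scored) {
    expect_equal(p$freq_pos, 1)
    expect_equal(p$freq_diff, abs(p$freq_pos - p$freq_neg))
  }
  # duplicates (same edge set from both groups) are merged
  dup <- c(pats, pats)
  expect_length(score_patterns(dup, pos, neg), length(pats))
})

test_that("discriminative selection is strict and deduplicated", {
  mk <- function(keys, d) {
    p <- mstmkl:::new_pattern(mstmkl:::keys_to_edges(keys), freq = 1)
    p$freq_pos <- d; p$freq_neg <- 0; p$freq_diff <- d
    p
  }
  pats <- list(mk("1-2", 0.10), mk("2-3", 0.13), mk("3-4", 0.14))
  out <- select_discriminative(pats, 0.13)
  expect_length(out, 1L)
  expect_equal(mstmkl:::edge_keys(out[[1]]$edges), "3-4")
  # T = 0 keeps every pattern with nonzero difference
  expect_length(select_discriminative(pats, 0), 3L)
  expect_error(select_discriminative(pats, -0.1), ">= 0")
  expect_length(select_discriminative(list(), 0.13), 0L)
})

test_that("an engineered cohort yields exactly the hand-computed survivors", {
  # patient group: edge 1-2 in 4/4, edge 2-3 in 3/4; control: 1-2 in 1/4
  pos <- list(labeled_graph(1:3, rbind(c(1, 2), c(2, 3))),
              labeled_graph(1:3, rbind(c(1, 2), c(2, 3))),
              labeled_graph(1:3, rbind(c(1, 2), c(2, 3))),
              labeled_graph(1:3, rbind(c(1, 2))))
  neg <- list(labeled_graph(1:3, rbind(c(1, 2))),
              labeled_graph(1:3, rbind(c(1, 3))),
              labeled_graph(1:3, rbind(c(1, 3))),
              labeled_graph(1:3, rbind(c(2, 3))))
  mined <- c(mine_frequent_subgraphs(pos, 0.7, mode = "all"),
             mine_frequent_subgraphs(neg, 0.7, mode = "all"))
  scored <- score_patterns(mined, pos, neg)
  # hand table: {1-2}: 1 - 0.25 = 0.75; {2-3}: 0.75 - 0.25 = 0.5;
  # {1-2,2-3}: 0.75 - 0 = 0.75 -- exactly two exceed T = 0.6
  out <- select_discriminative(scored, 0.6)
  expect_setequal(vapply(out, mstmkl:::pattern_key, ""),
                  c("1-2", "1-2|2-3"))
})

test_that("reconstruction intersects trees with selected pattern edges", {
  mst <- labeled_graph(1:5, cbind(1:4, 2:5))
  sel <- list(mstmkl:::new_pattern(rbind(c(1, 2), c(2, 3)), 1))
  rec <- reconstruct_networks(list(mst), sel)[[1]]
  expect_equal(mstmkl:::edge_keys(rec), c("1-2", "2-3"))
  expect_equal(rec$nodes, 1:5)  # isolated nodes kept
  # empty selection -> edgeless; full coverage -> identity
  expect_equal(nrow(reconstruct_networks(list(mst), list())[[1]]$edges), 0L)
  full <- list(mstmkl:::new_pattern(mst$edges, 1))
  expect_equal(mstmkl:::edge_keys(reconstruct_networks(list(mst), full)[[1]]),
               mstmkl:::edge_keys(mst))
})
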