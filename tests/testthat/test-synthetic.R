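test_that("group covariances are valid correlation matrices; null case identical", {
  spec <- synth_spec(R = 25, T_len = 100, n_pos = 5, n_neg = 5, seed = 61)
  for (g in c("positive", "negative")) {
    S <- build_group_covariance(spec, g)
    expect_equal(diag(S), rep(1, 25))
    expect_equal(S, t(S))
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
               1e-6 - 1e-9)
  }
  null_spec <- synth_spec(R = 25, T_len = 100, n_pos = 5, n_neg = 5,
                          hub_effect = 0, motif_effect = 0, seed = 61)
  expect_equal(build_group_covariance(null_spec, "positive"),
               build_group_covariance(null_spec, "negative"))
})

test_that("planted structure is deterministic given the seed", {
  s1 <- synth_spec(R = 20, n_pos = 3, n_neg = 3, seed = 62)
  s2 <- synth_spec(R = 20, n_pos = 3, n_neg = 3, seed = 62)
  expect_identical(s1$backbone, s2$backbone)
  expect_identical(s1$weights, s2$weights)
  expect_identical(s1$hubs, s2$hubs)
  expect_identical(s1$motif, s2$motif)
  c1 <- generate_cohort(s1); c2 <- generate_cohort(s2)
  expect_identical(c1$records[[1]]$timeseries, c2$records[[1]]$timeseries)
  expect_identical(c1$records[[6]]$timeseries, c2$records[[6]]$timeseries)
  # different seed -> different structure
  s3 <- synth_spec(R = 20, n_pos = 3, n_neg = 3, seed = 63)
  expect_false(identical(s1$weights, s3$weights))
})

test_that("hubs and motif are disjoint and the motif is connected", {
  for (sd_ in 64:68) {
    spec <- synth_spec(R = 30, n_pos = 3, n_neg = 3, seed = sd_)
    motif_nodes <- unique(as.vector(spec$motif))
    expect_length(intersect(spec$hubs, motif_nodes), 0)
    mg <- labeled_graph(motif_nodes, spec$motif)
    expect_true(mstmkl:::is_connected_graph(mg))
  }
})

test_that("sample correlations converge to the specified matrix at large T", {
  spec <- synth_spec(R = 20, T_len = 2000, n_pos = 2, n_neg = 2,
                     noise_sd = 0.05, seed = 65)
  co <- generate_cohort(spec)
  S <- build_group_covariance(spec, "positive")
  emp <- stats::cor(co$records[[1]]$timeseries)
  expect_lt(mean(abs(emp - S)[upper.tri(S)]), 0.05)
})

test_that("a strong motif lands in nearly every patient tree at large T", {
  spec <- synth_spec(R = 30, T_len = 500, n_pos = 40, n_neg = 2, seed = 66)
  co <- generate_cohort(spec)
  keys <- mstmkl:::edge_keys(spec$motif)
  pats <- co$records[seq_len(40)]
  rate <- mean(vapply(pats, function(r) {
    tk <- mstmkl:::edge_keys(subject_mst(r))
    all(keys %in% tk)
  }, TRUE))
  expect_gte(rate, 0.9)
})

test_that("under the null, region selection operates at the nominal level", {
  # replicated two-group cohorts with no planted effect: the t-test should
  # flag about alpha * R regions on average
  alpha <- 0.05; R <- 20
  counts <- vapply(1:40, function(i) {
    spec <- synth_spec(R = R, T_len = 60, n_pos = 10, n_neg = 10,
                       hub_effect = 0, motif_effect = 0, seed = 700 + i)
    ch <- mst_cohort(generate_cohort(spec)$records, "patient")
    sel <- suppressWarnings(select_regions(ch$B, ch$y, alpha = alpha))
    if (sel$fallback) 0L else length(sel$selected)
  }, 1L)
  expect_gt(mean(counts), alpha * R * 0.5)
  expect_lt(mean(counts), alpha * R * 1.5)
})

test_that("a repair that demotes the motif below background is rejected", {
  spec <- synth_spec(R = 10, n_pos = 2, n_neg = 2, seed = 67)
  S <- build_group_covariance(spec, "positive")
  expect_true(mstmkl:::motif_ordering_ok(S, spec))
  # corrupt one background correlation above the weakest motif edge
  bad <- S
  # craft a pair guaranteed to be background: non-hub nodes whose edge is
  # neither backbone nor motif
  all_pairs <- t(combn(setdiff(1:10, spec$hubs), 2))
  keys <- mstmkl:::edge_keys(all_pairs)
  used <- c(mstmkl:::edge_keys(spec$backbone), mstmkl:::edge_keys(spec$motif))
  free <- all_pairs[!keys %in% used, , drop = FALSE]
  skip_if(nrow(free) == 0)
  i <- free[1, 1]; j <- free[1, 2]
  bad[i, j] <- bad[j, i] <- min(S[spec$motif]) + 0.01
  expect_false(mstmkl:::motif_ordering_ok(bad, spec))
})

test_that("cohort writing round-trips byte-identically through the readers", {
  spec <- synth_spec(R = 8, T_len = 20, n_pos = 2, n_neg = 2, seed = 68)
  co <- generate_cohort(spec)
  d <- withr::local_tempdir()
  manifest <- write_cohort(co, d)
  recs <- read_manifest(manifest, "patient")
  expect_length(recs, 4L)
  expect_equal(recs[[1]]$timeseries, co$records[[1]]$timeseries,
               ignore_attr = TRUE)
  expect_identical(vapply(recs, function(r) r$group, ""),
                   vapply(co$records, function(r) r$group, ""))
  gt <- jsonlite::read_json(file.path(d, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(sort(gt$hubs), spec$hubs)
})
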