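# End-to-end behaviour of the fitted classifier and the repeated-CV driver
# on small synthetic cohorts (R = 20, 10/10 subjects) kept deliberately
# light; full-scale behaviour is exercised by the acceptance suite.

cohort <- tiny_cohort(R = 20, n = 10, seed = 71)

test_that("fitting exposes selection, patterns, beta and predicts its own data", {
  fit <- mstmkl(cohort, seed = 1)
  expect_s3_class(fit, "mstmkl")
  expect_true(fit$beta %in% seq(0, 1, by = 0.1))
  expect_s3_class(fit$selection, "region_selection")
  expect_true(length(fit$patterns) >= 1)
  pr <- predict(fit, cohort)
  expect_equal(nrow(pr), 20L)
  # resubstitution on a strongly planted cohort should be near-perfect
  expect_gte(mean(as.character(pr$predicted) == as.character(cohort$y)), 0.9)
  expect_output(print(fit), "mstmkl fit")
})

test_that("training artifacts ignore held-out subjects entirely", {
  tr <- cohort[c(1:8, 11:18)]
  fit1 <- mstmkl(tr, seed = 3)
  fit2 <- mstmkl(tr, seed = 3)  # same training set, fresh call
  expect_identical(fit1$selection, fit2$selection)
  expect_identical(lapply(fit1$patterns, mstmkl:::pattern_key),
                   lapply(fit2$patterns, mstmkl:::pattern_key))
  expect_identical(fit1$wl_train$vocab, fit2$wl_train$vocab)
  expect_identical(fit1$beta, fit2$beta)
  # predictions for one held-out subject do not depend on which other
  # held-out subjects are scored alongside it
  p_pair <- predict(fit1, cohort[c(9, 19)])
  p_solo <- predict(fit1, cohort[9])
  expect_equal(p_pair$score[1], p_solo$score[1])
})

test_that("fixed-beta endpoints reproduce the single-kernel pipelines", {
  tr <- cohort[c(1:8, 11:18)]
  te <- cohort[c(9, 10, 19, 20)]
  f_lp <- mstmkl(tr, method = "lp", seed = 2)
  f_b1 <- mstmkl(tr, beta = 1, seed = 2)
  expect_equal(predict(f_lp, te), predict(f_b1, te))
  f_tp <- mstmkl(tr, method = "tp", seed = 2)
  f_b0 <- mstmkl(tr, beta = 0, seed = 2)
  expect_equal(predict(f_tp, te), predict(f_b0, te))
})

test_that("inner beta search breaks ties toward the smallest beta", {
  set.seed(72)
  X <- rbind(matrix(rnorm(40, 2), 8), matrix(rnorm(40, -2), 8))
  K <- normalize_kernel(tcrossprod(X) + diag(0.1, 16))
  y <- factor(rep(c("con", "pat"), each = 8), levels = c("con", "pat"))
  # identical kernels -> every beta ties -> beta 0 chosen
  out <- mstmkl:::select_beta(K, K, y, seq(0, 1, by = 0.1), C = 1,
                              inner_folds = 4, seed = 9)
  expect_equal(out$beta, 0)
  expect_equal(length(unique(out$accuracy)), 1L)
})

test_that("repeated CV aggregates metrics and respects its invariants", {
  cv <- mstmkl_cv(cohort, folds = 5, repetitions = 2, seed = 4)
  expect_s3_class(cv, "mstmkl_cv")
  expect_named(cv$metrics, c("ACC", "SEN", "SPE", "AUC"))
  # every subject predicted exactly once per repetition
  for (r in seq_along(cv$folds)) {
    ids <- unlist(lapply(cv$folds[[r]], `[[`, "test_ids"))
    expect_setequal(ids, cohort$ids)
    expect_equal(length(ids), length(cohort$ids))
  }
  # accuracy identity per repetition
  for (r in seq_len(nrow(cv$per_repetition))) {
    row <- cv$per_repetition[r, ]
    P <- sum(cohort$y == "patient"); N <- sum(cohort$y == "control")
    expect_equal(row$ACC, (row$SEN * P + row$SPE * N) / (P + N))
  }
  expect_output(print(cv), "ACC")
  expect_s3_class(roc_points(cv), "data.frame")
})

test_that("identical seed and configuration reproduce the report exactly", {
  cv1 <- mstmkl_cv(cohort, folds = 5, repetitions = 2, seed = 8)
  cv2 <- mstmkl_cv(cohort, folds = 5, repetitions = 2, seed = 8)
  expect_identical(serialize(cv1, NULL), serialize(cv2, NULL))
  cv3 <- mstmkl_cv(cohort, folds = 5, repetitions = 2, seed = 9)
  expect_false(identical(cv1$folds, cv3$folds))
})

test_that("separable planted data reaches perfect within-repetition accuracy", {
  strong <- tiny_cohort(R = 20, T_len = 1000, n = 10, seed = 73,
                        hub_effect = 0.45, motif_effect = 0.85,
                        noise_sd = 0.05)
  # verify the separability precondition: the motif sits in every patient
  # tree and in no control tree
  spec <- synth_spec(R = 20, T_len = 1000, n_pos = 10, n_neg = 10,
                     seed = 73, hub_effect = 0.45, motif_effect = 0.85,
                     noise_sd = 0.05)
  mk <- mstmkl:::edge_keys(spec$motif)
  has_motif <- vapply(strong$msts, function(m)
    all(mk %in% mstmkl:::edge_keys(m)), TRUE)
  expect_true(all(has_motif[strong$y == "patient"]))
  expect_false(any(has_motif[strong$y == "control"]))
  cv <- mstmkl_cv(strong, folds = 5, repetitions = 1, seed = 1)
  expect_equal(unname(cv$per_repetition$ACC[1]), 1)
})

test_that("permuted labels collapse accuracy to chance", {
  set.seed(74)
  perm <- cohort
  perm$y <- sample(perm$y)
  cv <- suppressWarnings(mstmkl_cv(perm, folds = 5, repetitions = 3,
                                   seed = 5))
  expect_gt(cv$metrics[["ACC"]], 0.2)
  expect_lt(cv$metrics[["ACC"]], 0.8)
})
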