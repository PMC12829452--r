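# Fold construction, scaling, aggregation, and the LOSO engine.

test_that("LOSO folds cover every subject exactly once", {
  ids <- sprintf("S%02d", 1:20)
  folds <- make_loso_folds(ids)
  expect_length(folds, 20)
  tests <- vapply(folds, `[[`, character(1), "test_subject_id")
  expect_setequal(tests, ids)
  expect_false(anyDuplicated(tests) > 0)
  for (f in folds) {
    expect_false(f$test_subject_id %in% f$train_subject_ids)
    expect_setequal(c(f$test_subject_id, f$train_subject_ids), ids)
  }
  two <- make_loso_folds(c("B", "A"))
  expect_equal(two[[1]]$test_subject_id, "A")
  expect_length(two[[1]]$train_subject_ids, 1)
  expect_error(make_loso_folds(c("A", "A")), "duplicate")
  expect_error(make_loso_folds("A"), "at least 2")
})

test_that("fold scalers standardize training data and pass constants through", {
  set.seed(2)
  X <- matrix(rnorm(200, 5, 3), 40)
  sc <- fit_fold_scaler(X)
  Z <- apply_scaler(sc, X)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_equal(unname(apply(Z, 2, function(v) sqrt(mean((v - mean(v))^2)))),
               rep(1, 5))
  Xc <- cbind(X, 7)                       # constant feature
  sc2 <- fit_fold_scaler(Xc)
  expect_equal(unname(sc2$sd[6]), 1)
  expect_true(all(apply_scaler(sc2, Xc)[, 6] == 0))
})

test_that("fold scalers are independent of held-out data", {
  set.seed(3)
  feats <- list(A = matrix(rnorm(60), 10), B = matrix(rnorm(60), 10),
                C = matrix(rnorm(60), 10))
  train <- rbind(feats$A, feats$B)
  sc1 <- fit_fold_scaler(train)
  feats$C <- feats$C * 100 + 17           # mutate the held-out subject
  sc2 <- fit_fold_scaler(rbind(feats$A, feats$B))
  expect_identical(sc1, sc2)
})

test_that("subject aggregation follows the strict > 0.5 rule", {
  a <- aggregate_subject(c(0.6, 0.8), 1, "S01")
  expect_equal(a$score, 0.7)
  expect_equal(a$predicted, 1L)
  b <- aggregate_subject(c(0.5, 0.5), 1, "S02")
  expect_equal(b$score, 0.5)
  expect_equal(b$predicted, 0L)           # tie goes to class 0
  c_ <- aggregate_subject(0.2, 0, "S03")
  expect_equal(c_$score, 0.2)
  expect_equal(c_$predicted, 0L)
  expect_error(aggregate_subject(numeric(0), 1, "S04"), "S04")
})

# small synthetic feature cohort: per-subject Gaussian band-power-like
# features whose means differ by group (feature-space separability is
# obvious by construction: group means differ by 3 pooled SDs)
toy_feature_cohort <- function(n_per_group = 5, n_ep = 12, p = 6, shift = 3,
                               seed = 21) {
  eegcnn:::with_seed(seed, {
    ids <- sprintf("S%02d", seq_len(2 * n_per_group))
    groups <- rep(c(0L, 1L), each = n_per_group)
    feats <- lapply(seq_along(ids), function(i) {
      matrix(rnorm(n_ep * p, mean = shift * groups[i]), n_ep)
    })
    list(features = setNames(feats, ids),
         labels = setNames(groups, ids))
  })
}

test_that("the SVM engine recovers a strong feature-space group difference", {
  toy <- toy_feature_cohort()
  res <- run_loso(toy$features, toy$labels, "svm", seed = 4)
  ss <- res$subject_scores
  expect_equal(nrow(ss), 10)
  expect_setequal(ss$subject_id, names(toy$features))
  expect_gte(mean(ss$predicted == ss$truth), 0.9)
  expect_length(res$fold_records, 10)
  # pooled epoch metrics equal recomputation from the saved fold records
  probs <- unlist(lapply(res$fold_records, `[[`, "probs"))
  truth <- unlist(lapply(res$fold_records, `[[`, "epoch_truth"))
  expect_equal(res$epoch_accuracy, mean((probs > 0.5) == truth))
  expect_equal(res$epoch_auc, roc_auc(truth, probs))
  acc <- vapply(res$fold_records, `[[`, numeric(1), "epoch_accuracy")
  expect_equal(res$epoch_accuracy_mean, mean(acc))
  expect_equal(res$epoch_accuracy_sd, sd(acc))
})

test_that("without any group effect there is no positive subject-level discrimination", {
  # LOSO aggregation at tiny n is pessimistically biased, not centered at
  # 0.5: the held-out subject's own class has one fewer training subject,
  # tilting its epoch probabilities towards the other class. The honest
  # null statement is therefore one-sided: no real discrimination appears.
  toy <- toy_feature_cohort(shift = 0, seed = 31)
  res <- run_loso(toy$features, toy$labels, "svm", seed = 9)
  auc <- roc_auc(res$subject_scores$truth, res$subject_scores$score)
  expect_lte(auc, 0.75)
  # pooled epoch-level probabilities carry no signal either
  expect_lte(res$epoch_auc, 0.65)
})

test_that("CNN fold training is leakage-free under internal validation", {
  # tensors small enough for a fast end-to-end check
  make_feats <- function(mutate_last = FALSE) {
    eegcnn:::with_seed(41, {
      ids <- sprintf("S%02d", 1:6)
      feats <- lapply(1:6, function(i) {
        x <- array(rnorm(8 * 10 * 16 * 2), c(8, 10, 16, 2))
        if (i <= 3) x[, 3:4, 5:8, 1] <- x[, 3:4, 5:8, 1] + 2
        x
      })
      if (mutate_last) feats[[6]] <- feats[[6]] * 50 + 3
      list(features = setNames(feats, ids),
           labels = setNames(rep(c(0L, 1L), each = 3), ids))
    })
  }
  spec <- cnn_spec(max_train_epochs = 3, batch_size = 8, seed = 1,
                   early_stop = "internal_val", patience = 2)
  base <- make_feats(FALSE)
  mut <- make_feats(TRUE)
  r1 <- run_loso(base$features, base$labels, "cnn", cnn = spec, seed = 2)
  r2 <- run_loso(mut$features, mut$labels, "cnn", cnn = spec, seed = 2)
  # fold 6 holds out S06, the mutated subject: its scaler and the trained
  # weights must be identical across the two runs
  expect_identical(r1$fold_records[[6]]$scaler, r2$fold_records[[6]]$scaler)
  expect_identical(r1$fold_records[[6]]$fit_info$n_passes,
                   r2$fold_records[[6]]$fit_info$n_passes)
  # ... while its predictions (on different data) differ
  expect_false(identical(r1$fold_records[[6]]$probs,
                         r2$fold_records[[6]]$probs))
})

test_that("per-fold seeds make runs reproducible end to end", {
  toy <- toy_feature_cohort(n_per_group = 3)
  r1 <- run_loso(toy$features, toy$labels, "svm", seed = 5)
  r2 <- run_loso(toy$features, toy$labels, "svm", seed = 5)
  expect_identical(r1$subject_scores, r2$subject_scores)
})

test_that("subjects without epochs are rejected up front", {
  toy <- toy_feature_cohort(n_per_group = 2)
  toy$features[[1]] <- toy$features[[1]][0, , drop = FALSE]
  expect_error(run_loso(toy$features, toy$labels, "svm"), "no clean epochs")
})
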