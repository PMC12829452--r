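# Leave-one-subject-out orchestration: fold plans, leakage-safe per-fold
# standardization, epoch-to-subject probability aggregation, and run
# bookkeeping.

#' Build leave-one-subject-out fold plans
#'
#' One fold per subject (deterministic ordering by subject id); each fold
#' holds out every epoch of exactly one subject and trains on all others.
#'
#' @param subject_ids character vector of unique subject ids.
#' @return List of fold plans, each with `fold_id`, `test_subject_id`,
#'   `train_subject_ids`.
#' @export
make_loso_folds <- function(subject_ids) {
  if (anyDuplicated(subject_ids)) stopf("duplicate subject ids")
  if (length(subject_ids) < 2) stopf("need at least 2 subjects")
  ids <- sort(subject_ids)
  lapply(seq_along(ids), function(i) {
    list(fold_id = i, test_subject_id = ids[i],
         train_subject_ids = ids[-i])
  })
}

#' Per-fold feature standardization
#'
#' `fit_fold_scaler` estimates per-feature mean and scale on the training
#' epochs only (population SD; zero-variance features are centered but not
#' divided). `apply_scaler` applies those frozen parameters to any feature
#' matrix, so the held-out subject never influences the scaling.
#'
#' @param x `n_epochs x n_features` matrix.
#' @return For `fit_fold_scaler`: an object of class `fold_scaler`.
#' @export
fit_fold_scaler <- function(x) {
  x <- flatten_features(x)
  m <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, m)^2))
  s[s < 1e-12] <- 1
  structure(list(mean = m, sd = s), class = "fold_scaler")
}

#' @rdname fit_fold_scaler
#' @param scaler a `fold_scaler`.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "fold_scaler"))
  x <- flatten_features(x)
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, `/`)
}

#' Aggregate epoch probabilities into a subject-level score
#'
#' The subject score is the arithmetic mean of the subject's epoch
#' probabilities; the predicted label is 1 iff the score is strictly greater
#' than 0.5 (a tied score maps to class 0).
#'
#' @param probs numeric vector of epoch class-1 probabilities (non-empty).
#' @param truth the subject's true label (0/1).
#' @param subject_id subject identifier (for error messages and the result).
#' @return A one-row data frame: `subject_id`, `score`, `predicted`, `truth`.
#' @export
aggregate_subject <- function(probs, truth, subject_id = "?") {
  if (length(probs) == 0) {
    stopf("subject %s has no epoch probabilities to aggregate", subject_id)
  }
  score <- mean(probs)
  data.frame(subject_id = subject_id, score = score,
             predicted = as.integer(score > 0.5),
             truth = as.integer(truth), stringsAsFactors = FALSE)
}

#' Run leave-one-subject-out classification
#'
#' For each fold: fit the standardizer on the training epochs, fit the
#' classifier on the (standardized) training epochs, predict the held-out
#' subject's epochs, and aggregate them into a subject score. Per-fold seeds
#' derive deterministically from `seed + fold_id`, so results do not depend
#' on execution order.
#'
#' For the CNN with `early_stop = "internal_val"`, a subset of *training*
#' subjects (about 15%, at least one) is held aside as the early-stopping
#' monitor, so the stopping decision never sees the test subject. The
#' `"paper_faithful_test_monitor"` mode instead monitors the held-out
#' subject's epochs (leaky by construction; provided for protocol
#' comparison).
#'
#' @param features named list (one entry per subject) of epoch feature
#'   arrays: `(epochs, freqs, times, channels)` tensors for the CNN, or
#'   `(epochs, features)` band-power matrices for the SVM.
#' @param labels named binary vector of subject labels (0/1).
#' @param classifier `"cnn"` or `"svm"`.
#' @param cnn a [cnn_spec()] (CNN runs).
#' @param svm a [band_power_spec()] (SVM runs).
#' @param seed integer master seed.
#' @return An object of class `loso_result`: `subject_scores` (one row per
#'   subject), `fold_records` (per-fold epoch probabilities and accuracy),
#'   `epoch_accuracy_mean`/`_sd` across folds, and pooled epoch-level
#'   `epoch_accuracy` / `epoch_auc`.
#' @export
run_loso <- function(features, labels, classifier = c("cnn", "svm"),
                     cnn = cnn_spec(), svm = band_power_spec(), seed = 1) {
  classifier <- match.arg(classifier)
  ids <- names(features)
  if (is.null(ids)) stopf("features must be a named list keyed by subject id")
  if (!all(ids %in% names(labels))) stopf("labels missing for some subjects")
  n_ep <- vapply(features, function(f) dim(flatten_features(f))[1], numeric(1))
  if (any(n_ep < 1)) {
    stopf("subject(s) %s have no clean epochs",
          paste(ids[n_ep < 1], collapse = ", "))
  }
  folds <- make_loso_folds(ids)
  records <- vector("list", length(folds))
  scores <- vector("list", length(folds))
  for (f in folds) {
    res <- tryCatch(
      run_loso_fold(f, features, labels, classifier, cnn, svm, seed),
      error = function(e) e)
    if (inherits(res, "error")) {
      partial <- list(completed = records[!vapply(records, is.null, logical(1))])
      cond <- simpleError(sprintf("fold %d (test subject %s) failed: %s",
                                  f$fold_id, f$test_subject_id,
                                  conditionMessage(res)))
      cond$partial <- partial
      stop(cond)
    }
    records[[f$fold_id]] <- res$record
    scores[[f$fold_id]] <- res$score
  }
  subject_scores <- do.call(rbind, scores)
  fold_acc <- vapply(records, `[[`, numeric(1), "epoch_accuracy")
  pooled_probs <- unlist(lapply(records, `[[`, "probs"))
  pooled_truth <- unlist(lapply(records, `[[`, "epoch_truth"))
  structure(list(
    subject_scores = subject_scores,
    fold_records = records,
    classifier = classifier,
    seed = seed,
    epoch_accuracy_mean = mean(fold_acc),
    epoch_accuracy_sd = sd(fold_acc),
    epoch_accuracy = mean((pooled_probs > 0.5) == pooled_truth),
    epoch_auc = roc_auc(pooled_truth, pooled_probs)
  ), class = "loso_result")
}

#' @noRd
run_loso_fold <- function(fold, features, labels, classifier, cnn_sp, svm_sp,
                          seed) {
  fold_seed <- seed + fold$fold_id
  train_ids <- fold$train_subject_ids
  test_id <- fold$test_subject_id
  stack <- function(idset) {
    do.call(rbind, lapply(idset, function(id) flatten_features(features[[id]])))
  }
  x_test <- flatten_features(features[[test_id]])
  if (classifier == "cnn") {
    val_ids <- character(0)
    if (cnn_sp$early_stop == "internal_val") {
      n_val <- max(1L, round(cnn_sp$val_frac * length(train_ids)))
      val_ids <- with_seed(fold_seed,
                           sample(train_ids, min(n_val, length(train_ids) - 1L)))
    }
    fit_ids <- setdiff(train_ids, val_ids)
    x_all_train <- stack(train_ids)
    scaler <- fit_fold_scaler(x_all_train)
    x_fit <- apply_scaler(scaler, stack(fit_ids))
    y_fit <- rep(labels[fit_ids], vapply(fit_ids, function(id)
      dim(flatten_features(features[[id]]))[1], numeric(1)))
    dims <- dim(features[[fit_ids[1]]])[-1]
    spec <- cnn_sp
    spec$seed <- fold_seed
    model <- build_cnn(dims, spec)
    if (spec$early_stop == "internal_val") {
      x_val <- apply_scaler(scaler, stack(val_ids))
      y_val <- rep(labels[val_ids], vapply(val_ids, function(id)
        dim(flatten_features(features[[id]]))[1], numeric(1)))
      model <- fit_epoch_classifier(model, x_fit, y_fit, x_val, y_val)
    } else if (spec$early_stop == "paper_faithful_test_monitor") {
      model <- fit_epoch_classifier(model, x_fit, y_fit,
                                    apply_scaler(scaler, x_test),
                                    rep(labels[test_id], nrow(x_test)))
    } else {
      model <- fit_epoch_classifier(model, x_fit, y_fit)
    }
    probs <- predict_epoch_probabilities(model, apply_scaler(scaler, x_test))
    fit_info <- list(val_subjects = val_ids,
                     n_passes = max(model$history$pass))
  } else {
    x_train <- stack(train_ids)
    scaler <- fit_fold_scaler(x_train)
    y_train <- rep(labels[train_ids], vapply(train_ids, function(id)
      nrow(flatten_features(features[[id]])), numeric(1)))
    spec <- svm_sp
    spec$seed <- fold_seed
    model <- fit_svm(apply_scaler(scaler, x_train), y_train, spec)
    probs <- predict_svm_probabilities(model, apply_scaler(scaler, x_test))
    fit_info <- list()
  }
  truth <- labels[[test_id]]
  record <- list(fold_id = fold$fold_id, test_subject_id = test_id,
                 probs = probs,
                 epoch_truth = rep(as.integer(truth), length(probs)),
                 epoch_accuracy = mean((probs > 0.5) == truth),
                 scaler = scaler, fit_info = fit_info)
  list(record = record,
       score = aggregate_subject(probs, truth, test_id))
}

#' @export
print.loso_result <- function(x, ...) {
  ss <- x$subject_scores
  cat(sprintf(
    "<loso_result> %s, %d subjects: accuracy %.3f, AUC %.3f (epoch acc %.1f%% +/- %.1f%%)\n",
    x$classifier, nrow(ss), mean(ss$predicted == ss$truth),
    roc_auc(ss$truth, ss$score),
    100 * x$epoch_accuracy_mean, 100 * x$epoch_accuracy_sd))
  invisible(x)
}

#' Run the full cohort analysis pipeline
#'
#' Preprocesses every recording, extracts the classifier's features
#' (time-frequency tensors for the CNN, Welch band powers for the SVM), and
#' evaluates the classifier under leave-one-subject-out cross-validation.
#'
#' @param cohort an `eeg_cohort`.
#' @param preproc a [preproc_config()].
#' @param tfr a [tfr_config()] (CNN runs).
#' @param classifier `"cnn"` or `"svm"`.
#' @param epoch_sets optionally, precomputed `preprocess_cohort()` output to
#'   reuse across classifiers.
#' @inheritParams run_loso
#' @return A `loso_result` (see [run_loso()]); the preprocessed epochs are
#'   attached as `attr(, "epoch_sets")`.
#' @export
classify_cohort <- function(cohort, preproc = preproc_config(),
                            tfr = tfr_config(), classifier = c("cnn", "svm"),
                            cnn = cnn_spec(), svm = band_power_spec(),
                            seed = 1, epoch_sets = NULL) {
  classifier <- match.arg(classifier)
  if (is.null(epoch_sets)) epoch_sets <- preprocess_cohort(cohort, preproc)
  ids <- vapply(epoch_sets, `[[`, character(1), "subject_id")
  labels <- setNames(vapply(epoch_sets, `[[`, integer(1), "group"), ids)
  features <- setNames(lapply(epoch_sets, function(eps) {
    if (classifier == "cnn") tfr_features(eps, tfr)$data
    else band_power_features(eps, svm)
  }), ids)
  out <- run_loso(features, labels, classifier, cnn = cnn, svm = svm,
                  seed = seed)
  attr(out, "epoch_sets") <- epoch_sets
  out
}
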