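# Late-fusion (stacking) stage: subject-level EEG score + one clinical or
# demographic covariate at a time, combined by ridge-penalized logistic
# regression under the same leave-one-subject-out protocol.

FUSION_FEATURES <- c("docs_total", "mis_score", "bai_total", "bdi_total",
                     "age", "sex", "education")

#' Assemble the fusion table for one covariate
#'
#' Joins subject-level EEG scores with one covariate by subject id. Rows
#' with a missing covariate value are dropped (listwise deletion; the
#' remaining N is what fusion results report).
#'
#' @param scores data frame with `subject_id`, `score`, `truth` (e.g.
#'   `loso_result$subject_scores`).
#' @param covariates covariate table (one row per subject).
#' @param feature covariate name, one of `docs_total`, `mis_score`,
#'   `bai_total`, `bdi_total`, `age`, `sex`, `education`; `NULL` for the
#'   EEG-only baseline.
#' @return Data frame with `subject_id`, `eeg_score`, `feature` (absent for
#'   the baseline), `truth`.
#' @export
assemble_fusion_table <- function(scores, covariates, feature = NULL) {
  if (!all(scores$subject_id %in% covariates$subject_id)) {
    stopf("covariate table is missing some scored subjects")
  }
  if (!is.null(feature) && !feature %in% FUSION_FEATURES) {
    stopf("unknown feature '%s'; valid features: %s", feature,
          paste(FUSION_FEATURES, collapse = ", "))
  }
  idx <- match(scores$subject_id, covariates$subject_id)
  out <- data.frame(subject_id = scores$subject_id,
                    eeg_score = scores$score,
                    truth = as.integer(scores$truth),
                    stringsAsFactors = FALSE)
  if (!is.null(feature)) {
    out$feature <- covariates[[feature]][idx]
    out <- out[!is.na(out$feature), , drop = FALSE]
  }
  attr(out, "feature") <- feature %||% "baseline_eeg"
  out
}

# Newton/IRLS ridge logistic regression; intercept unpenalized, penalty
# 0.5 * lambda * ||w||^2 added to the summed log loss (lambda = 1 matches
# the conventional unit-strength default).
#' @noRd
ridge_logistic <- function(X, y, lambda = 1, maxit = 50, tol = 1e-9) {
  X <- cbind(`(Intercept)` = 1, X)
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - drop(pen %*% beta)
    H <- crossprod(X * w, X) + pen
    delta <- solve(H, grad)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  beta
}

#' @noRd
fusion_design <- function(rows, train_idx) {
  # numeric columns z-scored with training parameters; factors one-hot
  # encoded on the training levels (categories unseen in training map to
  # all-zero rows).
  cols <- list(eeg_score = rows$eeg_score)
  if (!is.null(rows$feature)) cols$feature <- rows$feature
  blocks_train <- list(); blocks_all <- list()
  for (nm in names(cols)) {
    v <- cols[[nm]]
    if (is.numeric(v)) {
      m <- mean(v[train_idx])
      s <- sqrt(mean((v[train_idx] - m)^2))
      if (s < 1e-12) s <- 1
      blocks_all[[nm]] <- matrix((v - m) / s, ncol = 1,
                                 dimnames = list(NULL, nm))
    } else {
      lv <- unique(as.character(v[train_idx]))
      oh <- vapply(lv, function(l) as.numeric(as.character(v) == l),
                   numeric(length(v)))
      oh <- matrix(oh, nrow = length(v),
                   dimnames = list(NULL, paste0(nm, "_", lv)))
      blocks_all[[nm]] <- oh
    }
  }
  do.call(cbind, blocks_all)
}

#' Evaluate one fusion model under leave-one-subject-out
#'
#' Per fold: the preprocessing (z-scoring of numeric inputs, one-hot
#' encoding of categorical inputs) is fitted on the training rows only, a
#' ridge logistic regression combines the EEG score with the covariate, and
#' the held-out subject's probability is predicted. Pooled predictions over
#' all folds yield AUC, accuracy and macro precision/recall/F1 (predicted
#' label = probability > 0.5). Folds whose training rows are single-class
#' are skipped and flagged.
#'
#' @param rows output of [assemble_fusion_table()].
#' @param seed integer seed (kept for interface symmetry; the fit is
#'   deterministic).
#' @param lambda ridge penalty on the non-intercept coefficients (0 = none).
#' @return An object of class `fusion_result` with `feature`, `n_used`,
#'   `auc`, `accuracy`, `precision`, `recall`, `f1`, `skipped_folds` and the
#'   per-subject `predictions`.
#' @export
run_fusion_loso <- function(rows, seed = 1, lambda = 1) {
  if (length(unique(rows$truth)) < 2 || min(table(rows$truth)) < 2) {
    stopf("need at least 2 subjects per class after missing-value handling")
  }
  design <- NULL
  folds <- make_loso_folds(rows$subject_id)
  preds <- rep(NA_real_, nrow(rows))
  skipped <- integer(0)
  for (f in folds) {
    ti <- which(rows$subject_id != f$test_subject_id)
    hi <- which(rows$subject_id == f$test_subject_id)
    if (length(unique(rows$truth[ti])) < 2) {
      skipped <- c(skipped, f$fold_id)
      next
    }
    X <- fusion_design(rows, ti)
    beta <- ridge_logistic(X[ti, , drop = FALSE], rows$truth[ti],
                           lambda = lambda)
    eta <- drop(cbind(1, X[hi, , drop = FALSE]) %*% beta)
    preds[hi] <- 1 / (1 + exp(-eta))
  }
  ok <- !is.na(preds)
  truth <- rows$truth[ok]
  predicted <- as.integer(preds[ok] > 0.5)
  cm <- confusion(truth, predicted)
  mr <- classification_metrics(cm)
  structure(list(
    feature = attr(rows, "feature"),
    n_used = nrow(rows),
    auc = roc_auc(truth, preds[ok]),
    accuracy = mr$accuracy,
    precision = mr$macro["precision"],
    recall = mr$macro["recall"],
    f1 = mr$macro["f1"],
    skipped_folds = skipped,
    predictions = data.frame(subject_id = rows$subject_id, prob = preds,
                             truth = rows$truth, stringsAsFactors = FALSE)
  ), class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> %s (N = %d): AUC %.2f, accuracy %.2f\n",
              x$feature, x$n_used, x$auc, x$accuracy))
  invisible(x)
}

#' Compare augmented fusion models to the EEG-only baseline
#'
#' Labels each augmented model `Improved` / `None` / `Worse` by comparing
#' its AUC to the baseline AUC at two-decimal reporting precision, in the
#' canonical covariate order (DOCS, MIS, BAI, BDI-II, age, sex, education).
#'
#' @param results list of `fusion_result`s for the augmented models.
#' @param baseline the EEG-only `fusion_result`.
#' @return Data frame with one row per model (baseline first).
#' @export
compare_to_baseline <- function(results, baseline) {
  order_key <- c("docs_total", "mis_score", "bai_total", "bdi_total",
                 "age", "sex", "education")
  feats <- vapply(results, `[[`, character(1), "feature")
  results <- results[order(match(feats, order_key))]
  row_of <- function(r, change) {
    data.frame(feature = r$feature, n = r$n_used,
               auc = r$auc, accuracy = r$accuracy,
               precision = as.numeric(r$precision),
               recall = as.numeric(r$recall), f1 = as.numeric(r$f1),
               change = change, stringsAsFactors = FALSE)
  }
  base_auc <- round(baseline$auc, 2)
  out <- row_of(baseline, "Baseline")
  for (r in results) {
    a <- round(r$auc, 2)
    change <- if (a > base_auc) "Improved" else if (a == base_auc) "None" else "Worse"
    out <- rbind(out, row_of(r, change))
  }
  rownames(out) <- NULL
  out
}
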