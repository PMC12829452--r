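# Classification metrics: confusion counts, per-class precision/recall/F1,
# accuracy, macro/weighted averages, ROC AUC, and table-style rendering.

#' Confusion counts for binary predictions
#'
#' @param truth,predicted equal-length binary (0/1) vectors.
#' @return An object of class `confusion_counts` with fields `tn`, `fp`,
#'   `fn`, `tp` (they partition the subjects).
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) stopf("length mismatch")
  if (!all(truth %in% c(0, 1)) || !all(predicted %in% c(0, 1))) {
    stopf("truth and predicted must be binary (0/1)")
  }
  structure(list(tn = sum(truth == 0 & predicted == 0),
                 fp = sum(truth == 0 & predicted == 1),
                 fn = sum(truth == 1 & predicted == 0),
                 tp = sum(truth == 1 & predicted == 1)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tn=%d fp=%d fn=%d tp=%d\n",
              x$tn, x$fp, x$fn, x$tp))
  invisible(x)
}

#' Classification report from confusion counts
#'
#' Per-class precision, recall, F1 and support, overall accuracy, and
#' macro (unweighted) / weighted (support-weighted) averages. A metric with
#' a zero denominator is reported as 0 and flagged.
#'
#' @param cm a `confusion_counts` object; both class supports must be
#'   positive.
#' @return An object of class `metrics_report`: `per_class` data frame
#'   (rows `HC (0)`, `OCD (1)`), `accuracy`, `macro`, `weighted`, `flags`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_counts"))
  n <- cm$tn + cm$fp + cm$fn + cm$tp
  support0 <- cm$tn + cm$fp
  support1 <- cm$fn + cm$tp
  if (support0 == 0 || support1 == 0) {
    stopf("both classes need positive support (got %d / %d)",
          support0, support1)
  }
  flags <- character(0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      flags <<- c(flags, sprintf("%s undefined (zero denominator), reported as 0", what))
      return(0)
    }
    num / den
  }
  prec0 <- safe_div(cm$tn, cm$tn + cm$fn, "precision of class 0")
  rec0 <- safe_div(cm$tn, support0, "recall of class 0")
  prec1 <- safe_div(cm$tp, cm$tp + cm$fp, "precision of class 1")
  rec1 <- safe_div(cm$tp, support1, "recall of class 1")
  f1_of <- function(p, r, what) {
    if (p + r == 0) {
      flags <<- c(flags, sprintf("%s undefined, reported as 0", what))
      return(0)
    }
    2 * p * r / (p + r)
  }
  f10 <- f1_of(prec0, rec0, "F1 of class 0")
  f11 <- f1_of(prec1, rec1, "F1 of class 1")
  per_class <- data.frame(
    class = c("HC (0)", "OCD (1)"),
    precision = c(prec0, prec1), recall = c(rec0, rec1),
    f1 = c(f10, f11), support = c(support0, support1),
    stringsAsFactors = FALSE)
  wts <- c(support0, support1) / n
  structure(list(
    per_class = per_class,
    accuracy = (cm$tp + cm$tn) / n,
    macro = c(precision = mean(per_class$precision),
              recall = mean(per_class$recall), f1 = mean(per_class$f1)),
    weighted = c(precision = sum(per_class$precision * wts),
                 recall = sum(per_class$recall * wts),
                 f1 = sum(per_class$f1 * wts)),
    n = n, flags = flags
  ), class = "metrics_report")
}

#' Area under the ROC curve
#'
#' Pairwise-concordance (Mann-Whitney) definition: the probability that a
#' random positive scores above a random negative, with ties counted 1/2.
#'
#' @param truth binary labels (both classes present).
#' @param scores numeric scores (higher = more class-1).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(truth, scores) {
  truth <- as.integer(truth)
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present to compute AUC")
  r <- rank(scores)                 # average ranks implement the tie rule
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Render a classification report as a table
#'
#' Table layout with per-class rows followed by accuracy, macro-average and
#' weighted-average rows, all rounded half-even to two decimals for display
#' (internal values keep full precision).
#'
#' @param metrics a `metrics_report`.
#' @param auc optional AUC appended as a footer line (text style).
#' @param style `"text"` for aligned plain text, `"csv"` for a data frame.
#' @return Character vector of lines (`"text"`) or a data frame (`"csv"`).
#' @export
render_report <- function(metrics, auc = NULL, style = c("text", "csv")) {
  stopifnot(inherits(metrics, "metrics_report"))
  style <- match.arg(style)
  pc <- metrics$per_class
  r2 <- function(x) sprintf("%.2f", round(x, 2))
  df <- data.frame(
    class = c(pc$class, "Accuracy", "Macro Avg", "Wtd Avg"),
    precision = c(r2(pc$precision), "", r2(metrics$macro["precision"]),
                  r2(metrics$weighted["precision"])),
    recall = c(r2(pc$recall), "", r2(metrics$macro["recall"]),
               r2(metrics$weighted["recall"])),
    f1 = c(r2(pc$f1), r2(metrics$accuracy), r2(metrics$macro["f1"]),
           r2(metrics$weighted["f1"])),
    support = c(pc$support, metrics$n, metrics$n, metrics$n),
    stringsAsFactors = FALSE)
  if (style == "csv") return(df)
  lines <- c(sprintf("%-10s %9s %7s %9s %8s", "CLASS", "PRECISION", "RECALL",
                     "F1-SCORE", "SUPPORT"),
             sprintf("%-10s %9s %7s %9s %8d", df$class, df$precision,
                     df$recall, df$f1, df$support))
  if (!is.null(auc)) lines <- c(lines, sprintf("AUC: %s", r2(auc)))
  lines
}
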