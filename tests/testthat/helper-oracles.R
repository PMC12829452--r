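# Independent metric oracles shared across test files.

# independent formula-level oracle in exact rational arithmetic (numerators
# and denominators kept as integers until the final division)
oracle_metrics <- function(tn, fp, fn, tp) {
  div <- function(a, b) if (b == 0) 0 else a / b
  p0 <- div(tn, tn + fn); r0 <- div(tn, tn + fp)
  p1 <- div(tp, tp + fp); r1 <- div(tp, tp + fn)
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  n <- tn + fp + fn + tp
  list(p0 = p0, r0 = r0, p1 = p1, r1 = r1, f10 = f1(p0, r0),
       f11 = f1(p1, r1), acc = (tn + tp) / n,
       macro_p = (p0 + p1) / 2,
       wtd_p = (p0 * (tn + fp) + p1 * (fn + tp)) / n)
}

# brute-force all-pairs AUC with the 1/2 tie convention
oracle_auc <- function(truth, scores) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

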