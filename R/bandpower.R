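# Welch band-power features and the RBF SVM baseline classifier.

#' Band-power / SVM baseline specification
#'
#' Canonical band definitions and the Welch / SVM settings of the baseline
#' classifier: per channel and epoch, the mean Welch spectral power in the
#' delta (1-4), theta (4-8), alpha (8-13), beta (13-30) and gamma (30-45 Hz)
#' bands; an RBF support vector machine with C = 1, the inverse
#' `n_features * var(X)` gamma rule, inverse-frequency class weights and
#' probability outputs.
#'
#' @param welch_segment Welch segment length in seconds (Hann window).
#' @param welch_overlap fractional overlap between consecutive segments.
#' @param cost SVM soft-margin constant.
#' @param seed integer seed (probability calibration shuffles internally).
#' @return An object of class `band_power_spec`.
#' @export
band_power_spec <- function(welch_segment = 2, welch_overlap = 0.5,
                            cost = 1.0, seed = 1) {
  spec <- list(bands = canonical_bands(), welch_segment = welch_segment,
               welch_overlap = welch_overlap, cost = cost,
               seed = as.integer(seed))
  class(spec) <- "band_power_spec"
  spec
}

#' Welch power spectral density
#'
#' Mean of modified periodograms over Hann-windowed, mean-detrended,
#' overlapping segments; one-sided density normalization.
#'
#' @param x numeric vector or channels-by-samples matrix.
#' @param sample_rate sampling rate (Hz).
#' @param segment segment length in seconds.
#' @param overlap fractional overlap in `[0, 1)`.
#' @return List with `freq` (Hz) and `psd` (channels x frequencies, power
#'   per Hz).
#' @export
welch_psd <- function(x, sample_rate, segment = 2, overlap = 0.5) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  S <- ncol(x)
  L <- round(segment * sample_rate)
  if (L > S) stopf("Welch segment (%d samples) longer than the signal (%d)", L, S)
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, S - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(L) - 1) / (L - 1)))  # Hann
  scale <- 1 / (sample_rate * sum(w^2))
  nf <- L %/% 2 + 1
  acc <- matrix(0, nrow(x), nf)
  for (s0 in starts) {
    seg <- x[, s0 + seq_len(L) - 1L, drop = FALSE]
    seg <- sweep(seg, 1, rowMeans(seg))           # constant detrend
    X <- stats::mvfft(t(seg * rep(w, each = nrow(seg))))
    P <- Mod(X[seq_len(nf), , drop = FALSE])^2 * scale
    P[2:(nf - 1), ] <- 2 * P[2:(nf - 1), ]        # one-sided
    acc <- acc + t(P)
  }
  list(freq = (seq_len(nf) - 1) * sample_rate / L,
       psd = acc / length(starts))
}

#' Band-power feature matrix of an epoch set
#'
#' Per epoch and channel, the Welch PSD is averaged over the frequency bins
#' whose center lies in `[band_low, band_high)` for each canonical band.
#' Feature order is channel-major, band-minor
#' (`ch1_delta, ch1_theta, ..., ch2_delta, ...`) and fixed.
#'
#' @param eps an `eeg_epochs` object.
#' @param spec a [band_power_spec()].
#' @return Matrix `n_epochs x (n_channels * 5)` with named columns.
#' @export
band_power_features <- function(eps, spec = band_power_spec()) {
  stopifnot(inherits(eps, "eeg_epochs"))
  d <- dim(eps$epochs)
  n_ep <- d[1]; n_ch <- d[2]
  bands <- spec$bands
  out <- matrix(0, n_ep, n_ch * length(bands))
  colnames(out) <- as.vector(t(outer(eps$channel_names, names(bands),
                                     paste, sep = "_")))
  for (e in seq_len(n_ep)) {
    sl <- eps$epochs[e, , , drop = FALSE]
    dim(sl) <- d[2:3]
    pw <- welch_psd(sl, eps$sample_rate, spec$welch_segment,
                    spec$welch_overlap)
    feats <- vapply(bands, function(b) {
      sel <- pw$freq >= b[1] & pw$freq < b[2]
      rowMeans(pw$psd[, sel, drop = FALSE])
    }, numeric(n_ch))                              # n_ch x n_band
    out[e, ] <- as.vector(t(feats))
  }
  out
}

#' Fit the band-power SVM baseline
#'
#' RBF-kernel SVM on (already standardized) band-power features, with the
#' `1 / (n_features * var(X))` gamma rule, inverse-frequency class weights
#' and Platt probability outputs.
#'
#' @param features `n_epochs x n_features` matrix (standardized upstream).
#' @param labels binary epoch labels (0/1), both classes present.
#' @param spec a [band_power_spec()].
#' @return An object of class `eeg_svm`.
#' @export
fit_svm <- function(features, labels, spec = band_power_spec()) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stopf("training labels contain a single class")
  v <- mean((features - mean(features))^2)
  gamma <- 1 / (ncol(features) * max(v, 1e-12))
  n <- length(labels)
  cw <- c("0" = n / (2 * sum(labels == 0)), "1" = n / (2 * sum(labels == 1)))
  fit <- with_seed(spec$seed,
    e1071::svm(x = features, y = factor(labels, levels = c("0", "1")),
               kernel = "radial", cost = spec$cost, gamma = gamma,
               class.weights = cw, probability = TRUE, scale = FALSE))
  structure(list(fit = fit, spec = spec), class = "eeg_svm")
}

#' @rdname fit_svm
#' @param model an `eeg_svm`.
#' @return For `predict_svm_probabilities`: numeric vector of class-1
#'   probabilities in `[0, 1]`, one per epoch.
#' @export
predict_svm_probabilities <- function(model, features) {
  stopifnot(inherits(model, "eeg_svm"))
  pr <- predict(model$fit, features, probability = TRUE)
  as.numeric(attr(pr, "probabilities")[, "1"])
}
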