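# Preprocessing: zero-phase FIR filtering, cropping, ICA-based ocular
# artifact removal, common-average referencing, overlapping epoching and
# peak-to-peak epoch rejection. Pipeline order is fixed and audited.

#' Preprocessing configuration
#'
#' @param notch_hz power-line notch frequency (Hz).
#' @param bandpass_low,bandpass_high band-pass edges (Hz).
#' @param crop_seconds uniform recording duration after cropping (s).
#' @param n_ica_components number of independent components to estimate.
#' @param eog_match_threshold z-score threshold above which a component's
#'   absolute correlation with an EOG channel marks it for removal.
#' @param epoch_length,epoch_overlap epoch window and overlap (s).
#' @param reject_p2p_uv peak-to-peak rejection threshold (microvolts); an
#'   epoch is kept iff every EEG channel stays at or below it.
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(notch_hz = 60, bandpass_low = 0.5,
                           bandpass_high = 50.0, crop_seconds = 240,
                           n_ica_components = 15, eog_match_threshold = 3.0,
                           epoch_length = 4, epoch_overlap = 2,
                           reject_p2p_uv = 300) {
  cfg <- list(notch_hz = notch_hz, bandpass_low = bandpass_low,
              bandpass_high = bandpass_high, crop_seconds = crop_seconds,
              n_ica_components = as.integer(n_ica_components),
              eog_match_threshold = eog_match_threshold,
              epoch_length = epoch_length, epoch_overlap = epoch_overlap,
              reject_p2p_uv = reject_p2p_uv)
  if (!(0 < cfg$bandpass_low && cfg$bandpass_low < cfg$bandpass_high)) {
    stopf("need 0 < bandpass_low < bandpass_high")
  }
  if (cfg$epoch_overlap < 0 || cfg$epoch_overlap >= cfg$epoch_length) {
    stopf("need 0 <= epoch_overlap < epoch_length")
  }
  if (cfg$reject_p2p_uv <= 0) stopf("reject_p2p_uv must be > 0")
  class(cfg) <- "preproc_config"
  cfg
}

# Windowed-sinc (Hamming) kernels: band-pass plus band-stop notch, convolved
# into one symmetric (exactly linear-phase) kernel. Transition bandwidths are
# auto-chosen from the cutoffs, mirroring common windowed-design semantics.
#' @noRd
design_fir_kernel <- function(cfg, fs) {
  nyq <- fs / 2
  if (cfg$bandpass_high >= nyq) {
    stopf("bandpass_high (%g Hz) must be below the Nyquist frequency (%g Hz)",
          cfg$bandpass_high, nyq)
  }
  trans_low <- min(max(cfg$bandpass_low * 0.25, 2), cfg$bandpass_low)
  odd <- function(n) { n <- max(3, round(n)); if (n %% 2 == 0) n + 1 else n }
  n_bp <- odd(3.3 * fs / trans_low)
  bp <- signal::fir1(n_bp - 1, c(cfg$bandpass_low, cfg$bandpass_high) / nyq,
                     type = "pass")
  kern <- as.numeric(bp)
  if (!is.null(cfg$notch_hz) && is.finite(cfg$notch_hz) &&
      cfg$notch_hz + 5 < nyq) {
    n_nt <- odd(3.3 * fs / 2)
    nt <- as.numeric(signal::fir1(n_nt - 1,
                                  c(cfg$notch_hz - 5, cfg$notch_hz + 5) / nyq,
                                  type = "stop"))
    kern <- convolve(kern, rev(nt), type = "open")
  }
  kern
}

# Zero-phase filtering of channel-by-sample matrices: FFT convolution with
# the symmetric kernel, output realigned by the exact group delay.
#' @noRd
apply_fir <- function(X, kern, chunk = 16L) {
  n <- ncol(X)
  L <- length(kern)
  delay <- (L - 1) / 2
  nfft <- 2^ceiling(log2(n + L - 1))
  K <- fft(c(kern, numeric(nfft - L)))
  out <- X
  idx <- seq_len(nrow(X))
  for (block in split(idx, ceiling(idx / chunk))) {
    xp <- rbind(t(X[block, , drop = FALSE]),
                matrix(0, nfft - n, length(block)))
    Y <- Re(stats::mvfft(stats::mvfft(xp) * K, inverse = TRUE)) / nfft
    out[block, ] <- t(Y[delay + seq_len(n), , drop = FALSE])
  }
  out
}

#' Filter a recording (notch + band-pass, zero-phase FIR)
#'
#' Applies a power-line notch followed by a band-pass filter, both
#' windowed-design FIR kernels applied with zero phase, to all EEG and EOG
#' channels. Output length equals input length.
#'
#' @param rec an `eeg_recording`.
#' @param cfg a [preproc_config()].
#' @return The filtered recording.
#' @export
filter_recording <- function(rec, cfg) {
  stopifnot(inherits(rec, "eeg_recording"))
  kern <- design_fir_kernel(cfg, rec$sample_rate)
  rec$eeg <- apply_fir(rec$eeg, kern)
  rec$eog <- apply_fir(rec$eog, kern)
  rec
}

#' Crop a recording to a uniform duration
#'
#' Retains the first `seconds * sample_rate` samples.
#'
#' @param rec an `eeg_recording`.
#' @param seconds target duration; recordings shorter than this raise an
#'   error naming the subject.
#' @return The cropped recording.
#' @export
crop_recording <- function(rec, seconds) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_keep <- round(seconds * rec$sample_rate)
  if (ncol(rec$eeg) < n_keep) {
    stopf("recording %s is shorter (%.1f s) than the requested crop (%g s)",
          rec$subject_id, ncol(rec$eeg) / rec$sample_rate, seconds)
  }
  rec$eeg <- rec$eeg[, seq_len(n_keep), drop = FALSE]
  rec$eog <- rec$eog[, seq_len(n_keep), drop = FALSE]
  if (!is.null(rec$events$blinks)) {
    rec$events$blinks <- rec$events$blinks[rec$events$blinks * rec$sample_rate <= n_keep]
  }
  if (!is.null(rec$events$noise_spans)) {
    keep <- rec$events$noise_spans[, "start"] <= n_keep
    rec$events$noise_spans <- rec$events$noise_spans[keep, , drop = FALSE]
    rec$events$noise_spans[, "end"] <- pmin(rec$events$noise_spans[, "end"], n_keep)
  }
  rec
}

#' Remove ocular independent components
#'
#' Decomposes the EEG into `n_ica_components` sources with FastICA
#' (`ica::icafast`, deterministic initialization), correlates each source
#' with every EOG channel, and iteratively removes components whose absolute
#' correlation is an outlier (z-score above `eog_match_threshold` among the
#' remaining components). The EEG is reconstructed from the surviving
#' components.
#'
#' @param rec an `eeg_recording` (filtered).
#' @param cfg a [preproc_config()].
#' @return The cleaned recording, with `rec$ica_report` listing the removed
#'   component indices, per-component EOG correlation scores and final
#'   z-scores.
#' @export
remove_ocular_components <- function(rec, cfg) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$eog) < 1) stopf("no EOG channel present; cannot match components")
  nc <- cfg$n_ica_components
  if (nc > nrow(rec$eeg)) {
    stopf("n_ica_components (%d) exceeds the EEG channel count (%d)",
          nc, nrow(rec$eeg))
  }
  X <- t(rec$eeg)                      # samples x channels
  dec <- ica::icafast(X, nc = nc, center = TRUE, maxit = 200, tol = 1e-6)
  if (!all(is.finite(dec$S)) || !all(is.finite(dec$M))) {
    stopf("ICA decomposition failed (non-finite sources); vafs = %s",
          paste(signif(dec$vafs, 3), collapse = ", "))
  }
  scores <- apply(abs(cor(dec$S, t(rec$eog))), 1, max)
  # leave-one-out z-score: each candidate is judged against the spread of
  # the OTHER surviving components, so a single strong ocular component is
  # detectable even with few components; an absolute correlation floor
  # keeps pure-noise outliers from being flagged.
  loo_z <- function(i, keep) {
    rest <- scores[setdiff(which(keep), i)]
    if (length(rest) < 2 || sd(rest) < 1e-12) return(0)
    (scores[i] - mean(rest)) / sd(rest)
  }
  removed <- logical(nc)
  repeat {
    keep <- !removed
    z <- vapply(seq_len(nc), loo_z, numeric(1), keep = keep)
    cand <- which(keep & z > cfg$eog_match_threshold & scores > 0.15)
    if (!length(cand)) break
    removed[cand[which.max(scores[cand])]] <- TRUE
  }
  z_final <- vapply(seq_len(nc), loo_z, numeric(1), keep = !removed)
  S_clean <- dec$S
  S_clean[, removed] <- 0
  center <- colMeans(X)
  X_clean <- tcrossprod(S_clean, dec$M) +
    matrix(center, nrow(X), ncol(X), byrow = TRUE)
  rec$eeg <- t(X_clean)
  rownames(rec$eeg) <- rec$channel_names
  rec$ica_report <- list(removed = which(removed), scores = scores,
                         z = z_final, n_components = nc)
  rec
}

#' Re-reference EEG channels to the common average
#'
#' Subtracts the instantaneous mean across EEG channels from every EEG
#' channel; EOG channels are untouched.
#'
#' @param rec an `eeg_recording` with at least two EEG channels.
#' @return The re-referenced recording.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$eeg) < 2) stopf("common average reference needs >= 2 EEG channels")
  rec$eeg <- sweep(rec$eeg, 2, colMeans(rec$eeg))
  rec
}

#' Segment a recording into overlapping fixed-length epochs
#'
#' Windows of `epoch_length` seconds are placed at onsets 0, S, 2S, ... with
#' step S = `epoch_length - epoch_overlap`; only fully contained windows are
#' emitted, giving `floor((T - L) / S) + 1` epochs. EEG channels only.
#'
#' @param rec an `eeg_recording`.
#' @param cfg a [preproc_config()].
#' @return An object of class `eeg_epochs` with fields `epochs`
#'   (n_epochs x channels x samples), `onsets` (s), and `kept_mask`.
#' @export
segment_epochs <- function(rec, cfg) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate
  L <- round(cfg$epoch_length * fs)
  S <- round((cfg$epoch_length - cfg$epoch_overlap) * fs)
  if (S <= 0) stopf("epoch_overlap must be smaller than epoch_length")
  n <- ncol(rec$eeg)
  if (n < L) stopf("recording shorter than one epoch")
  n_ep <- floor((n - L) / S) + 1
  eps <- array(0, c(n_ep, nrow(rec$eeg), L))
  onsets <- (seq_len(n_ep) - 1) * S
  for (e in seq_len(n_ep)) {
    eps[e, , ] <- rec$eeg[, onsets[e] + seq_len(L), drop = FALSE]
  }
  structure(list(subject_id = rec$subject_id, group = rec$group,
                 sample_rate = fs, epochs = eps, onsets = onsets / fs,
                 kept_mask = rep(TRUE, n_ep),
                 channel_names = rec$channel_names),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %s (group %d): %d epochs x %d ch x %d samples (%d kept of %d)\n",
              x$subject_id, x$group, dim(x$epochs)[1], dim(x$epochs)[2],
              dim(x$epochs)[3], sum(x$kept_mask), length(x$kept_mask)))
  invisible(x)
}

#' Reject epochs by peak-to-peak amplitude
#'
#' An epoch is kept iff the peak-to-peak amplitude of every EEG channel stays
#' at or below `reject_p2p_uv`. Order is preserved and decisions are recorded
#' in `kept_mask` (positions refer to the epochs passed in).
#'
#' @param eps an `eeg_epochs` object.
#' @param cfg a [preproc_config()].
#' @return The screened `eeg_epochs`; `attr(, "rejection")` holds the
#'   per-epoch maximum peak-to-peak values and the dropped indices.
#' @export
reject_epochs <- function(eps, cfg) {
  stopifnot(inherits(eps, "eeg_epochs"))
  n_ep <- dim(eps$epochs)[1]
  p2p <- vapply(seq_len(n_ep), function(e) {
    x <- eps$epochs[e, , , drop = FALSE]
    max(apply(x[1, , , drop = TRUE], 1, function(ch) max(ch) - min(ch)))
  }, numeric(1))
  keep <- p2p <= cfg$reject_p2p_uv
  out <- eps
  out$epochs <- eps$epochs[keep, , , drop = FALSE]
  out$onsets <- eps$onsets[keep]
  out$kept_mask <- keep
  attr(out, "rejection") <- list(p2p = p2p, dropped = which(!keep),
                                 threshold = cfg$reject_p2p_uv,
                                 empty = !any(keep))
  out
}

#' Preprocess one recording end to end
#'
#' Runs the fixed pipeline filter -> crop -> ICA ocular removal ->
#' common-average reference -> segment -> reject, and attaches an audit log
#' recording each step and its parameters in order.
#'
#' @param rec an `eeg_recording`.
#' @param cfg a [preproc_config()].
#' @return An `eeg_epochs` object with `attr(, "audit")` (ordered step log)
#'   and `attr(, "ica_report")`.
#' @export
preprocess_recording <- function(rec, cfg) {
  audit <- list()
  log_step <- function(name, ...) {
    audit[[length(audit) + 1]] <<- c(list(step = name), list(...))
  }
  rec <- filter_recording(rec, cfg)
  log_step("filter", notch_hz = cfg$notch_hz,
           bandpass = c(cfg$bandpass_low, cfg$bandpass_high),
           design = "windowed-sinc (Hamming), zero-phase")
  rec <- crop_recording(rec, cfg$crop_seconds)
  log_step("crop", seconds = cfg$crop_seconds)
  rec <- remove_ocular_components(rec, cfg)
  log_step("ica", n_components = cfg$n_ica_components,
           removed = rec$ica_report$removed,
           threshold = cfg$eog_match_threshold)
  rec <- common_average_reference(rec)
  log_step("reference", scheme = "common average")
  eps <- segment_epochs(rec, cfg)
  log_step("segment", length_s = cfg$epoch_length,
           overlap_s = cfg$epoch_overlap, n_epochs = dim(eps$epochs)[1])
  eps <- reject_epochs(eps, cfg)
  log_step("reject", p2p_uv = cfg$reject_p2p_uv,
           n_dropped = length(attr(eps, "rejection")$dropped))
  attr(eps, "audit") <- audit
  attr(eps, "ica_report") <- rec$ica_report
  eps
}

#' @rdname preprocess_recording
#' @param cohort an `eeg_cohort`.
#' @return For `preprocess_cohort`: a list of `eeg_epochs`, one per subject.
#' @export
preprocess_cohort <- function(cohort, cfg) {
  lapply(cohort$recordings, preprocess_recording, cfg = cfg)
}

#' Epochs overlapping ground-truth sample spans
#'
#' Maps sample intervals (e.g. injected noise-burst spans) onto the indices
#' of the epochs whose windows contain any sample of any span.
#'
#' @param onsets epoch onsets in seconds.
#' @param epoch_length epoch window length in seconds.
#' @param spans matrix with `start`/`end` columns (1-based sample indices).
#' @param sample_rate sampling rate (Hz).
#' @return Integer vector of epoch indices.
#' @export
epochs_overlapping_spans <- function(onsets, epoch_length, spans, sample_rate) {
  if (is.null(spans) || nrow(spans) == 0) return(integer(0))
  ep_start <- round(onsets * sample_rate) + 1
  ep_end <- ep_start + round(epoch_length * sample_rate) - 1
  hits <- vapply(seq_along(onsets), function(e) {
    any(spans[, "start"] <= ep_end[e] & spans[, "end"] >= ep_start[e])
  }, logical(1))
  which(hits)
}

#' Subject-level exclusion screen
#'
#' Separately from per-epoch rejection, subjects whose recordings fail a
#' stricter peak-to-peak criterion on a large fraction of epochs are flagged
#' for exclusion (persistent high-amplitude noise that ICA could not fix).
#'
#' @param epoch_sets list of `eeg_epochs` (pre-rejection).
#' @param p2p_uv subject-screening peak-to-peak threshold (microvolts).
#' @param max_bad_frac largest tolerated fraction of failing epochs.
#' @return Data frame with one row per subject: `subject_id`, `frac_bad`,
#'   `excluded`.
#' @export
subject_exclusion_report <- function(epoch_sets, p2p_uv = 250,
                                     max_bad_frac = 0.5) {
  rows <- lapply(epoch_sets, function(eps) {
    n_ep <- dim(eps$epochs)[1]
    bad <- vapply(seq_len(n_ep), function(e) {
      max(apply(eps$epochs[e, , , drop = TRUE], 1,
                function(ch) max(ch) - min(ch))) > p2p_uv
    }, logical(1))
    data.frame(subject_id = eps$subject_id, frac_bad = mean(bad),
               excluded = mean(bad) > max_bad_frac,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
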