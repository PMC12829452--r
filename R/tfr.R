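# Morlet wavelet time-frequency features.
#
# With n_cycles = f / cycles_divisor the temporal envelope width
# sigma_t = n_cycles / (2 pi f) = 1 / (2 pi cycles_divisor) is the same at
# every frequency, so all wavelets share one support and the transform at the
# decimated sample points reduces to a single windowed matrix product per
# epoch (exactly equal to full-resolution convolution subsampled at those
# points).

#' Time-frequency configuration
#'
#' @param f_min,f_max frequency range (Hz).
#' @param n_freqs number of logarithmically spaced frequencies.
#' @param cycles_divisor wavelet cycles rule: `n_cycles = f / cycles_divisor`.
#' @param decim temporal decimation factor (every `decim`-th TFR sample kept).
#' @param log_floor additive power offset for the log transform.
#' @param log_scale multiplier of the base-10 log (10 gives dB-like units).
#' @return An object of class `tfr_config`.
#' @export
tfr_config <- function(f_min = 1, f_max = 45, n_freqs = 40,
                       cycles_divisor = 2.0, decim = 16,
                       log_floor = 1e-10, log_scale = 10) {
  cfg <- list(f_min = f_min, f_max = f_max, n_freqs = as.integer(n_freqs),
              cycles_divisor = cycles_divisor, decim = as.integer(decim),
              log_floor = log_floor, log_scale = log_scale)
  if (!(0 < cfg$f_min && cfg$f_min < cfg$f_max)) stopf("need 0 < f_min < f_max")
  if (cfg$n_freqs < 2L) stopf("n_freqs must be >= 2")
  if (cfg$decim < 1L) stopf("decim must be >= 1")
  if (cfg$log_floor <= 0) stopf("log_floor must be > 0")
  class(cfg) <- "tfr_config"
  cfg
}

#' Logarithmically spaced analysis frequencies
#'
#' Geometric progression from `f_min` to `f_max` with a constant ratio
#' between consecutive values.
#'
#' @param cfg a [tfr_config()].
#' @return Numeric vector of length `n_freqs`, ascending.
#' @export
log_spaced_freqs <- function(cfg) {
  exp(seq(log(cfg$f_min), log(cfg$f_max), length.out = cfg$n_freqs))
}

# Complex Morlet wavelets on a shared time support, one column per
# frequency. Zero-mean corrected and L2-normalized.
#' @noRd
morlet_bank <- function(freqs, cfg, sample_rate, n_sigmas = 3.5) {
  sigma_t <- 1 / (2 * pi * cfg$cycles_divisor)
  half <- ceiling(n_sigmas * sigma_t * sample_rate)
  t <- (-half:half) / sample_rate
  env <- exp(-t^2 / (2 * sigma_t^2))
  W <- vapply(freqs, function(f) {
    correction <- exp(-(2 * pi * f * sigma_t)^2 / 2)
    w <- (exp(2i * pi * f * t) - correction) * env
    w / sqrt(sum(Mod(w)^2))
  }, complex(length(t)))
  W  # taps x n_freqs
}

#' Morlet wavelet power of an epoch set
#'
#' Squared magnitude of the complex Morlet transform, computed independently
#' for each EEG channel within each epoch, with the temporal axis decimated
#' by keeping every `decim`-th sample. No baseline correction is applied.
#'
#' @param eps an `eeg_epochs` object.
#' @param cfg a [tfr_config()].
#' @return An object of class `eeg_tfr` with `data` laid out channels-first:
#'   `(n_epochs, n_channels, n_freqs, n_times)`, plus `freqs` and `times`.
#' @export
morlet_power <- function(eps, cfg) {
  stopifnot(inherits(eps, "eeg_epochs"))
  fs <- eps$sample_rate
  if (cfg$f_max >= fs / 2) {
    stopf("f_max (%g Hz) must be below the Nyquist frequency (%g Hz)",
          cfg$f_max, fs / 2)
  }
  d <- dim(eps$epochs)
  n_ep <- d[1]; n_ch <- d[2]; n_s <- d[3]
  if (n_s %% cfg$decim != 0) {
    stopf("epoch length (%d samples) is not divisible by decim (%d)",
          n_s, cfg$decim)
  }
  freqs <- log_spaced_freqs(cfg)
  W <- morlet_bank(freqs, cfg, fs)
  taps <- nrow(W)
  half <- (taps - 1) / 2
  Wre <- Re(W); Wim <- Im(W)
  centers_sig <- seq(1L, n_s, by = cfg$decim)          # full-res pick indices
  n_t <- length(centers_sig)
  # window start index in the zero-padded signal (pad half on each side)
  starts <- as.integer(centers_sig)                    # (c - 1) - half + half + 1
  data <- array(0, c(n_ep, n_ch, cfg$n_freqs, n_t))
  pad <- matrix(0, half, n_ch)
  for (e in seq_len(n_ep)) {
    sl <- eps$epochs[e, , , drop = FALSE]
    dim(sl) <- c(n_ch, n_s)
    Xp <- rbind(pad, t(sl), pad)
    G <- window_gather(Xp, starts, taps)               # (n_t*n_ch) x taps
    P <- (G %*% Wre)^2 + (G %*% Wim)^2                 # (n_t*n_ch) x n_freqs
    dim(P) <- c(n_t, n_ch, cfg$n_freqs)
    data[e, , , ] <- aperm(P, c(2, 3, 1))
  }
  structure(list(subject_id = eps$subject_id, group = eps$group,
                 data = data, freqs = freqs,
                 times = (centers_sig - 1) / fs,
                 layout = "channels_first", log = FALSE,
                 config = cfg),
            class = "eeg_tfr")
}

#' @export
print.eeg_tfr <- function(x, ...) {
  cat(sprintf("<eeg_tfr> %s (group %d): %s, layout %s, %s\n",
              x$subject_id, x$group,
              paste(dim(x$data), collapse = " x "), x$layout,
              if (x$log) "log power" else "power"))
  invisible(x)
}

#' Log-transform a power tensor
#'
#' Elementwise `log_scale * log10(power + log_floor)` (defaults: dB-like
#' `10 * log10(power + 1e-10)`); strictly increasing in power.
#'
#' @param tfr an `eeg_tfr` holding non-negative power values.
#' @return The tensor with log power values (`tfr$log = TRUE`).
#' @export
log_power <- function(tfr) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  if (isTRUE(tfr$log)) stopf("tensor is already log-transformed")
  if (any(tfr$data < 0)) stopf("negative power values")
  cfg <- tfr$config
  tfr$data <- cfg$log_scale * log10(tfr$data + cfg$log_floor)
  tfr$log <- TRUE
  tfr
}

#' Permute a tensor to channels-last layout
#'
#' Pure permutation from `(epochs, channels, frequencies, times)` to
#' `(epochs, frequencies, times, channels)`; the multiset of values is
#' unchanged.
#'
#' @param tfr an `eeg_tfr` in channels-first layout.
#' @return The tensor in channels-last layout.
#' @export
to_channels_last <- function(tfr) {
  stopifnot(inherits(tfr, "eeg_tfr"))
  if (tfr$layout != "channels_first") {
    stopf("input must be in channels-first layout, got %s", tfr$layout)
  }
  if (length(dim(tfr$data)) != 4) stopf("expected a 4-d tensor")
  tfr$data <- aperm(tfr$data, c(1, 3, 4, 2))
  tfr$layout <- "channels_last"
  tfr
}

#' Full time-frequency feature pipeline for one subject
#'
#' Convenience wrapper: Morlet power, log transform, channels-last layout.
#'
#' @param eps an `eeg_epochs` object.
#' @param cfg a [tfr_config()].
#' @return A channels-last log-power `eeg_tfr`.
#' @export
tfr_features <- function(eps, cfg) {
  to_channels_last(log_power(morlet_power(eps, cfg)))
}
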