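#' Simulation configuration for synthetic EEG cohorts
#'
#' Bundles every knob of the synthetic cohort generator. The defaults mirror
#' a small resting-state case-control study: two balanced groups, 68 EEG and
#' 2 EOG channels sampled at 1024 Hz for 240 s, eyes-open background activity
#' (1/f-shaped noise plus an occipital-dominant 10 Hz rhythm), ocular blink
#' artifacts, sporadic high-amplitude noise segments, and a per-subject
#' clinical/demographic covariate table.
#'
#' @param n_per_group subjects per group (healthy controls = group 0,
#'   patients = group 1).
#' @param n_eeg_channels,n_eog_channels channel counts.
#' @param sample_rate sampling rate in Hz.
#' @param duration recording length in seconds.
#' @param effect_kind group effect to inject: `"none"`, `"band_power"`
#'   (multiplicative theta-band power elevation on a fixed fronto-central
#'   channel subset), or `"spectrotemporal"` (transient cross-channel bursts
#'   whose within-epoch timing and phase structure differ by group while each
#'   channel's long-run mean power in all five canonical bands is matched
#'   between groups by post-hoc per-band rescaling).
#' @param effect_size dimensionless effect scale, >= 0.
#' @param blink_rate ocular blink rate, events per minute.
#' @param noise_burst_prob probability of a high-amplitude noise burst per
#'   non-overlapping 4 s segment.
#' @param noise_burst_amplitude minimum peak-to-peak amplitude (microvolts)
#'   that an injected noise burst guarantees on at least one channel.
#' @param spectral_slope exponent beta of the 1/f^beta background spectrum.
#' @param covariate_separation scale on the between-group covariate mean
#'   differences (1 = the default group means, 0 = identical groups).
#' @param age_missing,mis_missing number of subjects with missing age /
#'   missing MIS scores in the covariate table.
#' @param preset `"full"` (the defaults above) or `"test"`, a desk-scale
#'   preset (8 EEG + 2 EOG channels, 256 Hz, 60 s) that keeps the full
#'   pipeline runnable in seconds.
#' @param seed integer seed; identical configurations yield bitwise-identical
#'   cohorts.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 10,
                       n_eeg_channels = 68,
                       n_eog_channels = 2,
                       sample_rate = 1024,
                       duration = 240,
                       effect_kind = c("none", "band_power", "spectrotemporal"),
                       effect_size = 1.0,
                       blink_rate = 12,
                       noise_burst_prob = 0.05,
                       noise_burst_amplitude = 400,
                       spectral_slope = 1.2,
                       covariate_separation = 1,
                       age_missing = 1,
                       mis_missing = 2,
                       preset = NULL,
                       seed = 1) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("full", "test"))
    if (preset == "test") {
      if (missing(n_eeg_channels)) n_eeg_channels <- 8
      if (missing(sample_rate)) sample_rate <- 256
      if (missing(duration)) duration <- 60
    }
  }
  effect_kind <- match.arg(effect_kind)
  cfg <- list(
    n_per_group = as.integer(n_per_group),
    n_eeg_channels = as.integer(n_eeg_channels),
    n_eog_channels = as.integer(n_eog_channels),
    sample_rate = sample_rate,
    duration = duration,
    effect_kind = effect_kind,
    effect_size = effect_size,
    blink_rate = blink_rate,
    noise_burst_prob = noise_burst_prob,
    noise_burst_amplitude = noise_burst_amplitude,
    spectral_slope = spectral_slope,
    covariate_separation = covariate_separation,
    age_missing = as.integer(age_missing),
    mis_missing = as.integer(mis_missing),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  if (cfg$n_per_group < 1L) stopf("n_per_group must be >= 1")
  if (cfg$sample_rate <= 0) stopf("sample_rate must be > 0")
  if (cfg$duration <= 0) stopf("duration must be > 0")
  if (cfg$noise_burst_prob < 0 || cfg$noise_burst_prob > 1) {
    stopf("noise_burst_prob must be in [0, 1]")
  }
  if (cfg$effect_size < 0) stopf("effect_size must be >= 0")
  if (cfg$blink_rate < 0) stopf("blink_rate must be >= 0")
  if (cfg$noise_burst_amplitude <= 0) stopf("noise_burst_amplitude must be > 0")
  if (cfg$spectral_slope <= 0) stopf("spectral_slope must be > 0")
  if (cfg$n_eog_channels < 1L) stopf("at least one EOG channel is required")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %d + %d subjects, %d EEG + %d EOG ch, %g Hz, %g s, effect %s (size %g), seed %d\n",
    x$n_per_group, x$n_per_group, x$n_eeg_channels, x$n_eog_channels,
    x$sample_rate, x$duration, x$effect_kind, x$effect_size, x$seed))
  invisible(x)
}
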