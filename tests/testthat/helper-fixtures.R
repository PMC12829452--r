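# Shared fixtures, built in code. Everything is seeded; helpers cache the
# more expensive objects for reuse across test files within one run.

test_sim_config <- function(...) {
  sim_config(preset = "test", ...)
}

test_preproc_config <- function(...) {
  args <- utils::modifyList(list(crop_seconds = 60, n_ica_components = 8),
                            list(...))
  do.call(preproc_config, args)
}

test_tfr_config <- function(...) {
  do.call(tfr_config, utils::modifyList(list(n_freqs = 16), list(...)))
}

# CNN settings used for the scaled-down study runs.
test_cnn_spec <- function(...) {
  args <- utils::modifyList(list(max_train_epochs = 12, patience = 3,
                                 min_train_epochs = 6), list(...))
  do.call(cnn_spec, args)
}

# a single tiny recording for unit tests (2 s of data are enough for most)
tiny_recording <- function(n_eeg = 4, n_eog = 2, fs = 256, dur = 8,
                           seed = 99) {
  cfg <- sim_config(n_per_group = 1, n_eeg_channels = n_eeg,
                    n_eog_channels = n_eog, sample_rate = fs, duration = dur,
                    effect_kind = "none", blink_rate = 0,
                    noise_burst_prob = 0, seed = seed)
  generate_cohort(cfg)$recordings[[1]]
}

# recording holding a single pure tone on every channel
tone_recording <- function(freq, fs = 256, dur = 8, n_eeg = 2, amp = 10) {
  t <- (seq_len(dur * fs) - 1) / fs
  eeg <- matrix(rep(amp * sin(2 * pi * freq * t), each = n_eeg), n_eeg)
  eog <- matrix(0, 2, length(t))
  eegcnn:::new_recording("tone", 0L, fs, eeg, eog)
}

# linearly separable toy tensors: two classes with Gaussian blobs imprinted
# at distinct time-frequency locations (verified separable by a linear
# probe in the classifier tests)
toy_tensors <- function(n_per_class = 40, H = 12, W = 20, C = 2, sd = 0.5,
                        seed = 5) {
  withr_seed <- function(code) eegcnn:::with_seed(seed, code)
  withr_seed({
    n <- 2 * n_per_class
    x <- array(rnorm(n * H * W * C, sd = sd), c(n, H, W, C))
    y <- rep(c(0, 1), each = n_per_class)
    for (i in seq_len(n)) {
      if (y[i] == 1) x[i, 3:5, 4:7, 1] <- x[i, 3:5, 4:7, 1] + 1.5
      else x[i, 8:10, 12:15, 2] <- x[i, 8:10, 12:15, 2] + 1.5
    }
    list(x = x, y = y)
  })
}

# cached scaled-down cohorts (shared by generator and classifier tests)
.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}
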