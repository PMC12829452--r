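# Filtering, cropping, ICA ocular removal, referencing, epoching, rejection.

test_that("the FIR filter attenuates the notch and passes the passband", {
  pp <- test_preproc_config()
  rms <- function(x) sqrt(mean(x^2))
  tone60 <- tone_recording(60)
  out60 <- filter_recording(tone60, pp)
  mid <- 512:1536                         # avoid the zero-padded edges
  expect_lt(rms(out60$eeg[1, mid]), 0.10 * rms(tone60$eeg[1, mid]))
  tone10 <- tone_recording(10)
  out10 <- filter_recording(tone10, pp)
  expect_equal(rms(out10$eeg[1, mid]), rms(tone10$eeg[1, mid]),
               tolerance = 0.1)
  # >= 20 dB attenuation at the notch relative to the passband
  expect_lt(rms(out60$eeg[1, mid]) / rms(tone60$eeg[1, mid]),
            10^(-20 / 20))
  zero <- tone_recording(10, amp = 0)
  expect_true(all(filter_recording(zero, pp)$eeg == 0))
  expect_error(filter_recording(tone10, preproc_config(bandpass_high = 200)),
               "Nyquist")
  # output length equals input length
  expect_equal(dim(out10$eeg), dim(tone10$eeg))
})

test_that("cropping keeps exactly the first seconds and validates length", {
  rec <- tiny_recording(dur = 10)
  out <- crop_recording(rec, 8)
  expect_equal(ncol(out$eeg), 8 * 256)
  expect_equal(out$eeg, rec$eeg[, 1:(8 * 256)])
  expect_equal(crop_recording(rec, 10)$eeg, rec$eeg)
  expect_error(crop_recording(rec, 12), "S01")
  # full-scale arithmetic: 300 s at 1024 Hz cropped to 240 s
  expect_equal(round(240 * 1024), 245760)
})

test_that("ICA removes blink components and reduces EOG-frontal coupling", {
  pp <- test_preproc_config()
  rec <- tiny_recording(n_eeg = 8, dur = 30)
  clean <- remove_ocular_components(filter_recording(rec, pp), pp)
  expect_length(clean$ica_report$removed, 0)

  blinky <- inject_blinks(rec, rate = 20, seed = 31)
  blinky_f <- filter_recording(blinky, pp)
  r_before <- max(abs(cor(t(blinky_f$eog), blinky_f$eeg[1, ])))
  fixed <- remove_ocular_components(blinky_f, pp)
  expect_gte(length(fixed$ica_report$removed), 1)
  expect_lte(length(fixed$ica_report$removed), pp$n_ica_components)
  r_after <- max(abs(cor(t(fixed$eog), fixed$eeg[1, ])))
  expect_lt(r_after, r_before)

  no_eog <- rec; no_eog$eog <- rec$eog[0, , drop = FALSE]
  expect_error(remove_ocular_components(no_eog, pp), "EOG")
  expect_error(remove_ocular_components(rec, preproc_config(n_ica_components = 20)),
               "exceeds")
})

test_that("common average referencing zeroes the channel mean and is idempotent", {
  rec <- tiny_recording(n_eeg = 6, dur = 4)
  # constant offset on all channels vanishes
  const <- rec; const$eeg[] <- 5
  expect_true(all(abs(common_average_reference(const)$eeg) < 1e-12))
  out <- common_average_reference(rec)
  expect_lt(max(abs(colMeans(out$eeg))), 1e-9)
  expect_equal(common_average_reference(out)$eeg, out$eeg)
  one_ch <- rec; one_ch$eeg <- rec$eeg[1, , drop = FALSE]
  expect_error(common_average_reference(one_ch), "2 EEG channels")
})

test_that("epoch counts follow floor((T - L)/S) + 1 with onsets 0, S, 2S, ...", {
  pp <- preproc_config(epoch_length = 4, epoch_overlap = 2)
  eps <- segment_epochs(tiny_recording(dur = 10), pp)
  expect_equal(dim(eps$epochs)[1], 4)
  expect_equal(eps$onsets, c(0, 2, 4, 6))
  eps1 <- segment_epochs(tiny_recording(dur = 4), pp)
  expect_equal(dim(eps1$epochs)[1], 1)
  # 240 s with 4 s / 2 s stepping gives 119 epochs
  expect_equal(floor((240 - 4) / 2) + 1, 119)
  expect_error(segment_epochs(tiny_recording(dur = 4),
                              preproc_config(epoch_length = 2,
                                             epoch_overlap = 2)),
               "overlap")
})

test_that("segment counts match a brute-force window-placement enumerator", {
  brute <- function(T, L, S) {
    n <- 0; onset <- 0
    while (onset + L <= T + 1e-9) { n <- n + 1; onset <- onset + S }
    n
  }
  set.seed(17)
  for (i in 1:200) {
    L <- sample(1:6, 1)
    S <- L - sample(seq(0, L - 0.5, by = 0.5), 1)
    T <- L + round(runif(1, 0, 30), 1)
    expect_equal(floor((T - L) / S) + 1e-9 + 1,
                 brute(T, L, S), tolerance = 1e-6)
  }
})

test_that("peak-to-peak rejection keeps epochs iff every channel is within bounds", {
  pp <- test_preproc_config(reject_p2p_uv = 300)
  rec <- tiny_recording(n_eeg = 3, dur = 12)
  rec$eeg <- rec$eeg / max(abs(rec$eeg)) * 50     # well within bounds
  eps <- segment_epochs(rec, pp)
  # boundary arithmetic: one channel spanning [-160, +145] has p2p 305
  eps$epochs[2, 2, 1] <- -160; eps$epochs[2, 2, 2] <- 145
  # all channels within [-149, +149] is kept
  eps$epochs[3, , ] <- pmin(pmax(eps$epochs[3, , ], -149), 149)
  out <- reject_epochs(eps, pp)
  expect_false(out$kept_mask[2])
  expect_true(out$kept_mask[3])
  expect_equal(attr(out, "rejection")$dropped, 2)
  # idempotent on the survivors
  again <- reject_epochs(out, pp)
  expect_true(all(again$kept_mask))
  expect_equal(again$epochs, out$epochs)
})

test_that("rejection decisions equal the generator's noise-burst ground truth", {
  cfg <- test_sim_config(n_per_group = 1, noise_burst_prob = 0.4,
                         blink_rate = 0, effect_kind = "none", seed = 12)
  coh <- generate_cohort(cfg)
  pp <- test_preproc_config()
  for (rec in coh$recordings) {
    eps <- segment_epochs(rec, pp)
    out <- reject_epochs(eps, pp)
    truth <- epochs_overlapping_spans(eps$onsets, pp$epoch_length,
                                      rec$events$noise_spans, rec$sample_rate)
    expect_equal(attr(out, "rejection")$dropped, truth)
  }
})

test_that("the pipeline runs in the fixed order and logs an audit trail", {
  cfg <- test_sim_config(n_per_group = 1, seed = 5)
  rec <- generate_cohort(cfg)$recordings[[1]]
  eps <- preprocess_recording(rec, test_preproc_config())
  audit <- attr(eps, "audit")
  expect_equal(vapply(audit, `[[`, character(1), "step"),
               c("filter", "crop", "ica", "reference", "segment", "reject"))
  expect_equal(audit[[5]]$n_epochs, 29)
  expect_s3_class(eps, "eeg_epochs")
  expect_true(all(is.finite(eps$epochs)))
})

test_that("referencing commutes with segmentation", {
  rec <- tiny_recording(n_eeg = 5, dur = 12)
  pp <- preproc_config(epoch_length = 4, epoch_overlap = 2)
  a <- segment_epochs(common_average_reference(rec), pp)
  b <- segment_epochs(rec, pp)
  b$epochs <- aperm(apply(b$epochs, c(1, 3), function(v) v - mean(v)),
                    c(2, 1, 3))
  expect_equal(a$epochs, b$epochs, tolerance = 1e-12)
})

test_that("subjects with persistent high-amplitude noise are flagged", {
  pp <- test_preproc_config()
  good <- tiny_recording(n_eeg = 3, dur = 12, seed = 1)
  bad <- tiny_recording(n_eeg = 3, dur = 12, seed = 2)
  bad$eeg[2, ] <- bad$eeg[2, ] + 400 * sin(2 * pi * 3 *
    seq_len(ncol(bad$eeg)) / bad$sample_rate)
  eset <- list(segment_epochs(good, pp), segment_epochs(bad, pp))
  rep_ <- subject_exclusion_report(eset, p2p_uv = 250)
  expect_equal(rep_$excluded, c(FALSE, TRUE))
})
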