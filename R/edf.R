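# Minimal EDF (16-bit) writer/reader for synthetic recordings, plus cohort
# sidecars (covariates CSV, ground-truth event JSON). This is a plain EDF
# dialect: ASCII headers, one-second data records, little-endian int16
# samples with per-channel physical scaling recorded in the header.

#' @noRd
edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' EEG and EOG channels are stored as 16-bit integers with per-channel
#' physical minima/maxima taken from the data; the subject id and group
#' label travel in the patient identification field. Sample counts are
#' truncated to whole one-second records.
#'
#' @param rec an `eeg_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sample_rate
  if (fs != round(fs)) stopf("EDF writer requires an integer sample rate")
  X <- rbind(rec$eeg, rec$eog)
  labels <- c(rec$channel_names, rec$eog_names)
  ns <- nrow(X)
  n_rec <- floor(ncol(X) / fs)
  X <- X[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(X, 1, min)
  pmax_ <- apply(X, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edf_pad(x, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr(sprintf("%s group=%d", rec$subject_id, rec$group), 80)
  wr("synthetic resting-state EEG", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("synthetic", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in pmin_) wr(sprintf("%.8g", v), 8)
  for (v in pmax_) wr(sprintf("%.8g", v), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("HP:0.1Hz", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- (r - 1) * fs + seq_len(fs)
    for (s in seq_len(ns)) {
      dig <- round((X[s, idx] - pmin_[s]) / scale[s] + dmin)
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return An `eeg_recording`; EOG channels are recognized by their
#'   `EOG` label prefix.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)
  patient <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  X <- matrix(0, ns, n_rec * spr[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2, endian = "little")
      X[s, (r - 1) * spr[s] + seq_len(spr[s])] <-
        (dig - dmin[s]) * scale[s] + pmin_[s]
    }
  }
  m <- regmatches(patient, regexec("^(\\S+) group=(\\d)", patient))[[1]]
  subject_id <- if (length(m)) m[2] else patient
  group <- if (length(m)) as.integer(m[3]) else NA_integer_
  is_eog <- startsWith(labels, "EOG")
  new_recording(subject_id, group, spr[1] / rec_dur,
                X[!is_eog, , drop = FALSE], X[is_eog, , drop = FALSE])
}

#' Write a cohort to disk (EDF + sidecars)
#'
#' One EDF file per subject, a `covariates.csv` table, and a
#' `ground_truth.json` sidecar with the generator's event metadata (blink
#' times, noise-burst spans, effect kind/size).
#'
#' @param cohort an `eeg_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings) {
    write_edf(rec, file.path(dir, paste0(rec$subject_id, ".edf")))
  }
  write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
            row.names = FALSE)
  truth <- lapply(cohort$recordings, function(rec) {
    ns <- rec$events$noise_spans
    list(subject_id = rec$subject_id, group = rec$group,
         blinks = rec$events$blinks,
         noise_spans = if (!is.null(ns)) as.data.frame(ns),
         burst_onsets = rec$events$burst_onsets)
  })
  jsonlite::write_json(
    list(effect_kind = cohort$config$effect_kind,
         effect_size = cohort$config$effect_size, subjects = truth),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @return For `read_cohort`: an `eeg_cohort` (recordings quantized by the
#'   16-bit container; event metadata restored from the sidecar).
#' @export
read_cohort <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.edf$", full.names = TRUE))
  recordings <- lapply(files, read_edf)
  covariates <- read.csv(file.path(dir, "covariates.csv"),
                         stringsAsFactors = TRUE)
  covariates$subject_id <- as.character(covariates$subject_id)
  truth_path <- file.path(dir, "ground_truth.json")
  config <- NULL
  if (file.exists(truth_path)) {
    gt <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    by_id <- setNames(seq_along(recordings),
                      vapply(recordings, `[[`, character(1), "subject_id"))
    for (i in seq_len(nrow(gt$subjects))) {
      s <- gt$subjects[i, ]
      j <- by_id[[s$subject_id]]
      recordings[[j]]$events$blinks <- unlist(s$blinks)
      if (!is.null(s$noise_spans[[1]])) {
        ns <- as.matrix(as.data.frame(s$noise_spans[[1]]))
        rownames(ns) <- NULL
        recordings[[j]]$events$noise_spans <- ns
      }
      recordings[[j]]$events$burst_onsets <- unlist(s$burst_onsets)
    }
    config <- list(effect_kind = gt$effect_kind, effect_size = gt$effect_size)
  }
  structure(list(recordings = recordings, covariates = covariates,
                 config = config),
            class = "eeg_cohort")
}
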