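## Minimal EDF (European Data Format) support: continuous 16-bit recordings
## with 1-second data records, plus the tab-separated annotation sidecar and
## subjects.tsv used throughout the pipeline. Covers the subset of EDF needed
## for round-tripping synthetic recordings; no EDF+ annotations signals.

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with one-second data records; per-channel physical scaling is
#' chosen from the data range, so the round-trip error is bounded by the
#' 16-bit quantization step. The sampling rate must be a whole number.
#'
#' @param recording an `eeg_recording`.
#' @param path output file path.
#' @param annotation_path optional path for the tab-separated annotation
#'   sidecar (columns onset_s, duration_s, state).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, annotation_path = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate
  if (fs != round(fs)) stop("sampling rate must be an integer for EDF export", call. = FALSE)
  data <- recording$data
  ns <- nrow(data)
  n_rec <- floor(ncol(data) / fs)
  if (n_rec < 1) stop("recording shorter than one data record", call. = FALSE)
  data <- data[, seq_len(n_rec * fs), drop = FALSE]

  phys_min <- apply(data, 1, min); phys_max <- apply(data, 1, max)
  pad <- pmax((phys_max - phys_min) * 1e-3, 1e-6)
  phys_min <- floor((phys_min - pad) * 1000) / 1000
  phys_max <- ceiling((phys_max + pad) * 1000) / 1000
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(recording$subject$subject_id, 80),
    edf_field("synthetic EEG", 80),
    edf_field("01.01.26", 8), edf_field("00.00.00", 8),
    edf_field(256 + 256 * ns, 8),
    edf_field("", 44),
    edf_field(n_rec, 8), edf_field(1, 8), edf_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  labels <- recording$channel_labels
  writeChar(paste(vapply(labels, edf_field, "", width = 16), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(edf_field("AgAgCl electrode", 80), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(edf_field("uV", 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(vapply(phys_min, edf_field, "", width = 8), collapse = ""), con, eos = NULL)
  writeChar(paste(vapply(phys_max, edf_field, "", width = 8), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(edf_field(dig_min, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(edf_field(dig_max, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(edf_field("BP 1-45Hz", 80), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(edf_field(fs, 8), ns), collapse = ""), con, eos = NULL)
  writeChar(paste(rep(edf_field("", 32), ns), collapse = ""), con, eos = NULL)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- vapply(seq_len(ns), function(ch) {
      as.integer(round((data[ch, idx] - phys_min[ch]) * scale[ch]) + dig_min)
    }, integer(fs))
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  if (!is.null(annotation_path)) {
    utils::write.table(recording$annotations, annotation_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

read_edf_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)          # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  rates <- spr / rec_dur
  if (length(unique(rates)) != 1) {
    stop("channels have differing sampling rates", call. = FALSE)
  }
  data <- matrix(0, ns, n_rec * spr[1], dimnames = list(labels, NULL))
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2, endian = "little")
      idx <- ((r - 1) * spr[ch] + 1):(r * spr[ch])
      data[ch, idx] <- (dig - dig_min[ch]) * scale[ch] + phys_min[ch]
    }
  }
  list(labels = labels, sampling_rate = rates[1], data = data)
}

read_annotation_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty annotation file", call. = FALSE)
  header <- strsplit(lines[1], "\t")[[1]]
  need <- c("onset_s", "duration_s", "state")
  if (!all(need %in% header)) {
    stop("annotation file must have columns onset_s, duration_s, state", call. = FALSE)
  }
  rows <- lapply(seq_along(lines)[-1], function(i) {
    parts <- strsplit(lines[i], "\t")[[1]]
    if (length(parts) != length(header)) {
      stop(sprintf("malformed annotation row at line %d", i), call. = FALSE)
    }
    row <- as.list(parts)
    names(row) <- header
    onset <- suppressWarnings(as.numeric(row$onset_s))
    dur <- suppressWarnings(as.numeric(row$duration_s))
    if (is.na(onset) || is.na(dur)) {
      stop(sprintf("non-numeric onset/duration at line %d", i), call. = FALSE)
    }
    data.frame(onset_s = onset, duration_s = dur, state = row$state,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read an EDF recording with its annotation sidecar
#'
#' Channel labels are normalized (case-insensitive, "EEG " prefixes and
#' reference suffixes stripped, legacy T3/T4/T5/T6 synonyms mapped to
#' T7/T8/P7/P8). If `channels` is supplied, the recording is restricted to
#' those electrodes and a channel-missing error names any absent labels.
#'
#' @param edf_path path to the EDF file.
#' @param annotation_path optional path to the tab-separated annotation
#'   sidecar (onset_s, duration_s, state); validated for overlap and bounds.
#' @param metadata_row optional single-row data.frame (e.g. from
#'   subjects.tsv) used to populate the subject profile.
#' @param channels optional electrode labels to require and select.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(edf_path, annotation_path = NULL,
                           metadata_row = NULL, channels = NULL) {
  raw <- read_edf_raw(edf_path)
  labels <- normalize_channel_label(raw$labels)
  rownames(raw$data) <- labels
  if (!is.null(channels)) {
    channels <- normalize_channel_label(channels)
    missing <- setdiff(channels, labels)
    if (length(missing)) {
      stop("missing required electrode(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    raw$data <- raw$data[channels, , drop = FALSE]
    labels <- channels
  }
  ann <- if (!is.null(annotation_path)) {
    read_annotation_tsv(annotation_path)
  } else {
    data.frame(onset_s = 0, duration_s = ncol(raw$data) / raw$sampling_rate,
               state = "EC", stringsAsFactors = FALSE)
  }
  subject <- if (!is.null(metadata_row)) {
    subject_profile(
      metadata_row$subject_id,
      group = metadata_row$group,
      age_years = metadata_row$age_years,
      handedness = metadata_row$handedness,
      seizure_hemisphere = metadata_row$seizure_hemisphere,
      blink_rate = if (!is.null(metadata_row$blink_rate)) metadata_row$blink_rate else 0,
      medications = if (nzchar(metadata_row$medications %||% "")) {
        strsplit(metadata_row$medications, ";")[[1]]
      } else character()
    )
  } else {
    subject_profile("unknown", group = "healthy")
  }
  new_recording(subject, raw$sampling_rate, labels, raw$data, ann)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a cohort to disk as EDF + sidecars
#'
#' Produces `<id>.edf` and `<id>_annotations.tsv` per subject plus a
#' `subjects.tsv` metadata table.
#'
#' @param cohort list of recordings from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort) {
    id <- rec$subject$subject_id
    write_edf(rec, file.path(dir, paste0(id, ".edf")),
              file.path(dir, paste0(id, "_annotations.tsv")))
  }
  md <- attr(cohort, "metadata")
  if (!is.null(md)) {
    utils::write.table(md, file.path(dir, "subjects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
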