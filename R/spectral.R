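## Multitaper spectral estimation and the sixteen normalized alpha-power
## fraction features (8 bipolar channels x 2 alpha sub-bands, log domain).

.dpss_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed as the leading eigenvectors of the standard symmetric
#' tridiagonal formulation, which shares eigenvectors with the Toeplitz
#' concentration problem; tapers are unit-energy and sign-fixed so that each
#' taper's mean (odd tapers: first moment) is non-negative. Results are
#' cached per (n, nw, k).
#'
#' @param n number of samples.
#' @param nw time-bandwidth product (default 4).
#' @param k number of tapers; must satisfy `k <= 2*nw - 1`.
#' @return n x k matrix of tapers (columns).
#' @export
dpss_tapers <- function(n, nw = 4, k = 7) {
  if (k > 2 * nw - 1) {
    stop("n_tapers must be <= 2*time_bandwidth - 1", call. = FALSE)
  }
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(.dpss_cache[[key]])) return(.dpss_cache[[key]])
  w <- nw / n
  i <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  A <- diag(diag_main)
  A[cbind(1:(n - 1), 2:n)] <- off
  A[cbind(2:n, 1:(n - 1))] <- off
  ev <- eigen(A, symmetric = TRUE)
  tapers <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    s <- if (j %% 2 == 1) sum(tapers[, j]) else sum(tapers[, j] * i)
    if (s < 0) tapers[, j] <- -tapers[, j]
  }
  .dpss_cache[[key]] <- tapers
  tapers
}

#' Multitaper power spectral density of a window
#'
#' Per-channel unity-weighted average of Slepian eigenspectra; the one-sided
#' density integrates (over 0 to Nyquist) to the signal variance.
#'
#' @param data channels x samples matrix (or a vector for one channel).
#' @param sampling_rate sampling rate in Hz.
#' @param time_bandwidth time-bandwidth product NW (default 4).
#' @param n_tapers number of tapers K (default 7); `K <= 2 NW - 1`.
#' @return a `power_spectrum`: list with `freqs_hz` (grid from 0 to
#'   Nyquist), `psd` (channels x frequencies, one-sided density) and the
#'   taper parameters.
#' @export
multitaper_psd <- function(data, sampling_rate, time_bandwidth = 4, n_tapers = 7) {
  if (!is.matrix(data)) data <- matrix(data, 1)
  n <- ncol(data)
  nch <- nrow(data)
  tapers <- dpss_tapers(n, time_bandwidth, n_tapers)
  n_keep <- floor(n / 2) + 1L
  freqs <- (seq_len(n_keep) - 1) * sampling_rate / n
  ## taper every channel by every taper, FFT all columns at once
  tap_big <- matrix(0, n, nch * n_tapers)
  for (ch in seq_len(nch)) {
    cols <- ((ch - 1) * n_tapers + 1):(ch * n_tapers)
    tap_big[, cols] <- tapers * data[ch, ]
  }
  spec <- abs(mvfft(tap_big))^2 / sampling_rate   # two-sided eigenspectra
  psd <- matrix(0, nch, n_keep, dimnames = list(rownames(data), NULL))
  fold <- rep(2, n_keep)
  fold[1] <- 1
  if (n %% 2 == 0) fold[n_keep] <- 1   # Nyquist bin is not duplicated
  for (ch in seq_len(nch)) {
    cols <- ((ch - 1) * n_tapers + 1):(ch * n_tapers)
    psd[ch, ] <- rowMeans(spec[seq_len(n_keep), cols, drop = FALSE]) * fold
  }
  structure(
    list(freqs_hz = freqs, psd = psd, sampling_rate = sampling_rate,
         time_bandwidth = time_bandwidth, n_tapers = n_tapers),
    class = "power_spectrum"
  )
}

#' Alpha band specifications
#'
#' The two disjoint alpha sub-bands used as features: low-alpha 7.5-10.5 Hz
#' and high-alpha 10.5-13.5 Hz, each normalized by the wide band 0.5-40 Hz.
#' Splitting the alpha band at 10.5 Hz lets a downstream model see slowing
#' (relatively more low-alpha) as well as overall alpha reduction.
#'
#' @param name band name.
#' @param lo_hz,hi_hz band edges in Hz.
#' @param wideband two-element numeric, the normalization band (default
#'   `c(0.5, 40)`).
#' @return a `band_spec` list.
#' @export
band_spec <- function(name, lo_hz, hi_hz, wideband = c(0.5, 40)) {
  if (lo_hz >= hi_hz) stop("need lo_hz < hi_hz", call. = FALSE)
  if (lo_hz < wideband[1] || hi_hz > wideband[2]) {
    stop("band must lie within the wideband", call. = FALSE)
  }
  structure(list(name = name, lo_hz = lo_hz, hi_hz = hi_hz, wideband = wideband),
            class = "band_spec")
}

#' @rdname band_spec
#' @export
default_bands <- function() {
  list(low_alpha = band_spec("low_alpha", 7.5, 10.5),
       high_alpha = band_spec("high_alpha", 10.5, 13.5))
}

## Trapezoidal integral of a PSD row between lo and hi, with the PSD linearly
## interpolated at the exact band edges so adjacent bands tile exactly.
trapz_band <- function(freqs, psd, lo, hi) {
  inside <- freqs > lo & freqs < hi
  f <- c(lo, freqs[inside], hi)
  p <- c(approx(freqs, psd, xout = lo)$y, psd[inside], approx(freqs, psd, xout = hi)$y)
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Fraction of spectral power within a band
#'
#' Band power divided by wide-band (0.5-40 Hz) power, both by trapezoidal
#' integration on the PSD grid with linear interpolation at the exact band
#' edges.
#'
#' @param spectrum a `power_spectrum`.
#' @param band a [band_spec()].
#' @return numeric vector of fractions in `(0, 1]`, one per channel.
#' @export
band_fraction <- function(spectrum, band) {
  stopifnot(inherits(spectrum, "power_spectrum"), inherits(band, "band_spec"))
  if (max(spectrum$freqs_hz) < band$wideband[2]) {
    stop("spectrum does not cover the wideband", call. = FALSE)
  }
  vapply(seq_len(nrow(spectrum$psd)), function(ch) {
    wide <- trapz_band(spectrum$freqs_hz, spectrum$psd[ch, ],
                       band$wideband[1], band$wideband[2])
    if (wide <= 0) stop("zero wide-band power: fraction undefined", call. = FALSE)
    trapz_band(spectrum$freqs_hz, spectrum$psd[ch, ], band$lo_hz, band$hi_hz) / wide
  }, numeric(1))
}

#' Compute the 16 log alpha-power-fraction features of a window
#'
#' Channel-major, band-minor ordering: for each bipolar channel in montage
#' order, the log low-alpha fraction then the log high-alpha fraction.
#' Features are invariant to any positive rescaling of the window samples.
#'
#' @param window an `epoch_window` (or a channels x samples matrix with a
#'   `sampling_rate` argument).
#' @param bands list of two [band_spec()]s (default [default_bands()]).
#' @param sampling_rate required when `window` is a bare matrix.
#' @param time_bandwidth,n_tapers multitaper parameters.
#' @return a `feature_vector`: list with subject_id, window_index, state and
#'   `values`, a named numeric vector of 16 log-fractions.
#' @export
compute_features <- function(window, bands = default_bands(),
                             sampling_rate = NULL, time_bandwidth = 4,
                             n_tapers = 7) {
  if (inherits(window, "epoch_window")) {
    data <- window$data
    fs <- window$sampling_rate
    sid <- window$subject_id
    widx <- window$window_index
    state <- window$state
  } else {
    data <- window
    fs <- sampling_rate
    if (is.null(fs)) stop("sampling_rate required for a bare matrix", call. = FALSE)
    sid <- NA_character_; widx <- NA_integer_; state <- NA_character_
  }
  spec <- multitaper_psd(data, fs, time_bandwidth, n_tapers)
  fracs <- vapply(bands, function(b) band_fraction(spec, b),
                  numeric(nrow(data)))
  if (!is.matrix(fracs)) fracs <- matrix(fracs, nrow = 1)
  chn <- rownames(data)
  if (is.null(chn)) chn <- paste0("ch", seq_len(nrow(data)))
  values <- as.numeric(t(log(fracs)))          # channel-major, band-minor
  names(values) <- as.vector(t(outer(chn, names(bands), paste, sep = ".")))
  structure(
    list(subject_id = sid, window_index = widx, state = state, values = values),
    class = "feature_vector"
  )
}

#' Tidy feature table for one recording
#'
#' Runs the full per-subject pipeline: band-pass filter, bipolar montage,
#' z-scored windows, multitaper features. Returns one row per
#' (window, channel, band).
#'
#' @param recording an `eeg_recording` with referential channels.
#' @param montage a [montage_spec()].
#' @param bands list of [band_spec()]s.
#' @param states annotation states to process (default `"EC"`).
#' @param filter apply [bandpass_filter()] first (default TRUE).
#' @param window_s window length in seconds.
#' @param time_bandwidth,n_tapers multitaper parameters.
#' @return data.frame with columns subject_id, window_index, state, channel,
#'   band, log_fraction.
#' @export
subject_feature_table <- function(recording, montage = default_montage(),
                                  bands = default_bands(), states = "EC",
                                  filter = TRUE, window_s = 10,
                                  time_bandwidth = 4, n_tapers = 7) {
  if (filter) {
    recording$data <- bandpass_filter(recording$data, recording$sampling_rate)
  }
  bip <- to_bipolar(recording, montage)
  out <- list()
  for (st in states) {
    windows <- extract_windows(bip, state = st, window_s = window_s)
    for (w in windows) {
      fv <- compute_features(w, bands, time_bandwidth = time_bandwidth,
                             n_tapers = n_tapers)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = fv$subject_id, window_index = fv$window_index,
        state = fv$state,
        channel = rep(montage$channel, each = length(bands)),
        band = rep(names(bands), times = nrow(montage)),
        log_fraction = unname(fv$values),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(subject_id = character(), window_index = integer(),
                      state = character(), channel = character(),
                      band = character(), log_fraction = numeric()))
  }
  do.call(rbind, out)
}

#' Feature table for a whole synthetic cohort
#'
#' Synthesizes each subject in turn (recordings are discarded after feature
#' extraction, keeping memory flat), runs the pipeline and binds the tidy
#' feature tables. Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param states annotation states to process (default `"EC"`).
#' @param ... passed to [subject_feature_table()].
#' @return data.frame of features with the cohort metadata attached as the
#'   `metadata` attribute.
#' @export
cohort_feature_table <- function(config, states = "EC", ...) {
  md <- cohort_metadata(config)
  profiles <- attr(md, "profiles")
  out <- vector("list", length(profiles))
  for (i in seq_along(profiles)) {
    rec <- synthesize_subject(profiles[[i]], config,
                              seed = subject_seed(config$seed, i))
    out[[i]] <- subject_feature_table(rec, states = states, ...)
  }
  features <- do.call(rbind, out)
  attr(features, "metadata") <- md
  features
}

#' Wide feature matrix from a tidy feature table
#'
#' One row per window, one column per feature in the canonical channel-major,
#' band-minor order; row metadata returned alongside.
#'
#' @param features tidy feature table.
#' @param montage a [montage_spec()] fixing the channel order.
#' @param band_names band order (default low then high alpha).
#' @return list with `matrix` (windows x 16) and `index` (data.frame of
#'   subject_id, window_index, state per row).
#' @export
feature_matrix <- function(features, montage = default_montage(),
                           band_names = c("low_alpha", "high_alpha")) {
  feat_names <- as.vector(t(outer(montage$channel, band_names, paste, sep = ".")))
  features$feature <- paste(features$channel, features$band, sep = ".")
  key <- paste(features$subject_id, features$window_index, features$state, sep = "\r")
  ukey <- unique(key)
  mat <- matrix(NA_real_, length(ukey), length(feat_names),
                dimnames = list(NULL, feat_names))
  row_of <- match(key, ukey)
  col_of <- match(features$feature, feat_names)
  if (anyNA(col_of)) stop("feature table contains unknown channel/band", call. = FALSE)
  mat[cbind(row_of, col_of)] <- features$log_fraction
  first <- !duplicated(key)
  index <- data.frame(
    subject_id = features$subject_id[first],
    window_index = features$window_index[first],
    state = features$state[first],
    stringsAsFactors = FALSE
  )
  list(matrix = mat, index = index)
}
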