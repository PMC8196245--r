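## Synthetic EEG cohort generator: 1/f background, posteriorly dominant
## band-limited alpha (stronger eyes-closed), group-level fronto-temporal
## alpha reduction, hemisphere-asymmetric reduction for lateralized subjects,
## and stereotyped eye-blink artefacts in eyes-open segments.

#' Subject profile for the synthetic cohort generator
#'
#' Describes one simulated participant: group membership, demographics, a
#' per-region/per-hemisphere alpha amplitude multiplier and the eye-blink
#' rate used for eyes-open segments.
#'
#' @param subject_id character scalar.
#' @param group one of `"healthy"`, `"patient"`, `"comparison"`.
#' @param age_years age in years.
#' @param handedness `"left"` or `"right"`.
#' @param seizure_hemisphere `"left"`, `"right"` or `"none"`. Must be
#'   `"none"` unless `group = "patient"` (only patients can be lateralized).
#' @param alpha_scale strictly positive multiplier applied to alpha
#'   amplitude; either a scalar or a 4 x 2 matrix with rownames
#'   `frontal/temporal/parietal/occipital` and colnames `left/right`.
#' @param blink_rate expected blinks per minute in eyes-open segments (>= 0).
#' @param medications character vector of medication flags.
#' @return an object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, group = c("healthy", "patient", "comparison"),
                            age_years = 30, handedness = c("right", "left"),
                            seizure_hemisphere = "none", alpha_scale = 1,
                            blink_rate = 10, medications = character()) {
  group <- match.arg(group)
  handedness <- match.arg(handedness)
  seizure_hemisphere <- match.arg(seizure_hemisphere, c("none", "left", "right"))
  if (seizure_hemisphere != "none" && group != "patient") {
    stop("only patients can have a seizure hemisphere", call. = FALSE)
  }
  regions <- c("frontal", "temporal", "parietal", "occipital")
  if (is.matrix(alpha_scale)) {
    if (!identical(rownames(alpha_scale), regions) ||
        !identical(colnames(alpha_scale), c("left", "right"))) {
      stop("alpha_scale matrix must have rownames ", paste(regions, collapse = "/"),
           " and colnames left/right", call. = FALSE)
    }
  } else {
    alpha_scale <- matrix(alpha_scale, 4, 2,
                          dimnames = list(regions, c("left", "right")))
  }
  if (any(alpha_scale <= 0)) stop("alpha_scale must be strictly positive", call. = FALSE)
  if (blink_rate < 0) stop("blink_rate must be >= 0", call. = FALSE)
  structure(
    list(subject_id = as.character(subject_id), group = group,
         age_years = age_years, handedness = handedness,
         seizure_hemisphere = seizure_hemisphere, alpha_scale = alpha_scale,
         blink_rate = blink_rate, medications = medications),
    class = "subject_profile"
  )
}

#' Cohort configuration
#'
#' Fixes the study conditions under which a synthetic cohort is generated:
#' group sizes, segment plan, sampling rate, channel set, the sizes of the
#' group-level alpha reductions and the random seed.
#'
#' @param n_per_group named integer vector with any of the entries
#'   `healthy`, `patient`, `lateralized`, `comparison`. `lateralized`
#'   subjects belong to the patient group but carry a seizure-hemisphere
#'   label (alternating left/right).
#' @param n_ec,n_eo number of eyes-closed / eyes-open segments per subject.
#' @param segment_s segment duration in seconds (positive multiple of 1 s).
#' @param sampling_rate sampling rate in Hz (>= 128).
#' @param channel_set referential electrode labels to synthesize. Must cover
#'   the 14 electrodes of the default bipolar montage; Fp1/Fp2 are included
#'   by default as the blink channels.
#' @param effect_size fractional alpha reduction in patients, in `[0, 1)`.
#'   The reduction is concentrated fronto-temporally: parieto-occipital
#'   channels receive 0.4 times the fractional reduction.
#' @param lateral_effect additional fractional reduction applied to the
#'   seizure hemisphere of lateralized patients, in `[0, 1)`.
#' @param noise_exponent spectral slope of the 1/f-type background, in `[0, 2]`.
#' @param alpha_freq,alpha_bw centre frequency and bandwidth (Hz) of the
#'   band-limited alpha oscillation.
#' @param blink_rate default blinks/minute for all subjects.
#' @param left_hand_fraction fraction of patients simulated left-handed.
#' @param seed integer seed making the cohort fully reproducible.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(healthy = 10, patient = 5),
                          n_ec = 8, n_eo = 8, segment_s = 60,
                          sampling_rate = 250,
                          channel_set = c("Fp1", "Fp2", REQUIRED_ELECTRODES),
                          effect_size = 0.3, lateral_effect = 0.2,
                          noise_exponent = 1, alpha_freq = 10, alpha_bw = 2,
                          blink_rate = 10, left_hand_fraction = 0.1,
                          seed = 1L) {
  known <- c("healthy", "patient", "lateralized", "comparison")
  if (is.null(names(n_per_group)) || !all(names(n_per_group) %in% known)) {
    stop("n_per_group must be named with groups among: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  if (any(n_per_group < 1)) stop("n_per_group values must be >= 1", call. = FALSE)
  if (segment_s <= 0 || segment_s != round(segment_s)) {
    stop("segment_s must be a positive whole number of seconds", call. = FALSE)
  }
  if (sampling_rate < 128) stop("sampling_rate must be >= 128 Hz", call. = FALSE)
  channel_set <- normalize_channel_label(channel_set)
  missing <- setdiff(REQUIRED_ELECTRODES, channel_set)
  if (length(missing)) {
    stop("channel_set must cover the montage electrodes; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (effect_size < 0 || effect_size >= 1) stop("effect_size must be in [0, 1)", call. = FALSE)
  if (lateral_effect < 0 || lateral_effect >= 1) stop("lateral_effect must be in [0, 1)", call. = FALSE)
  if (noise_exponent < 0 || noise_exponent > 2) stop("noise_exponent must be in [0, 2]", call. = FALSE)
  structure(
    list(n_per_group = n_per_group, n_ec = n_ec, n_eo = n_eo,
         segment_s = segment_s, sampling_rate = sampling_rate,
         channel_set = channel_set, effect_size = effect_size,
         lateral_effect = lateral_effect, noise_exponent = noise_exponent,
         alpha_freq = alpha_freq, alpha_bw = alpha_bw,
         blink_rate = blink_rate, left_hand_fraction = left_hand_fraction,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

## Spectral-shaping helper: colour white Gaussian noise so that power follows
## the supplied non-negative weight function of frequency, then return the
## real time series (weights are applied symmetrically on the DFT grid).
shape_noise <- function(n_samples, sampling_rate, weight_fun) {
  x <- rnorm(n_samples)
  f <- seq(0, n_samples - 1) * sampling_rate / n_samples
  f <- pmin(f, sampling_rate - f)  # fold to [0, Nyquist]
  w <- weight_fun(f)
  Re(fft(fft(x) * w, inverse = TRUE)) / n_samples
}

#' Generate power-law-spectrum background noise
#'
#' Each channel is an independent realization of noise whose power spectral
#' density is proportional to `1/f^noise_exponent` over 0.5-40 Hz (flat below
#' 0.5 Hz, zero mean), normalized to unit sample variance per channel.
#'
#' @param duration_s duration in seconds (> 0).
#' @param sampling_rate sampling rate in Hz (>= 128).
#' @param n_channels number of channels.
#' @param noise_exponent spectral slope in `[0, 2]`.
#' @param seed optional integer seed for reproducibility.
#' @return `n_channels` x `duration_s * sampling_rate` numeric matrix.
#' @export
generate_background <- function(duration_s, sampling_rate, n_channels = 1,
                                noise_exponent = 1, seed = NULL) {
  if (duration_s <= 0) stop("duration_s must be > 0", call. = FALSE)
  if (sampling_rate < 128) stop("sampling_rate must be >= 128 Hz", call. = FALSE)
  if (noise_exponent < 0 || noise_exponent > 2) {
    stop("noise_exponent must be in [0, 2]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * sampling_rate)
  wf <- function(f) {
    fc <- pmax(f, 0.5)               # flatten below 0.5 Hz
    w <- fc^(-noise_exponent / 2)
    w[f == 0] <- 0                   # zero mean
    w
  }
  out <- matrix(0, n_channels, n)
  for (ch in seq_len(n_channels)) {
    y <- shape_noise(n, sampling_rate, wf)
    out[ch, ] <- (y - mean(y)) / sd(y)
  }
  out
}

#' Generate a band-limited alpha oscillation
#'
#' Returns a stochastic narrow-band signal: Gaussian noise spectrally shaped
#' by a Gaussian band centred at `center_freq_hz` (power concentrated within
#' roughly `center_freq_hz` +/- 1.5 `bandwidth_hz`), scaled to the requested
#' RMS amplitude. A band-limited noise process (rather than a pure sinusoid)
#' gives multitaper power estimates realistic variance.
#'
#' @param duration_s duration in seconds.
#' @param sampling_rate sampling rate in Hz.
#' @param center_freq_hz centre frequency (7.5-13.5 Hz recommended).
#' @param bandwidth_hz bandwidth (> 0); the shaping amplitude is Gaussian
#'   with standard deviation `bandwidth_hz / 2`.
#' @param amplitude RMS amplitude of the returned signal (>= 0).
#' @param seed optional integer seed.
#' @return numeric vector of `duration_s * sampling_rate` samples.
#' @export
generate_alpha_component <- function(duration_s, sampling_rate,
                                     center_freq_hz = 10, bandwidth_hz = 2,
                                     amplitude = 1, seed = NULL) {
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  if (bandwidth_hz <= 0) stop("bandwidth_hz must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration_s * sampling_rate)
  if (amplitude == 0) return(numeric(n))
  wf <- function(f) exp(-0.5 * ((f - center_freq_hz) / (bandwidth_hz / 2))^2)
  y <- shape_noise(n, sampling_rate, wf)
  y <- y - mean(y)
  amplitude * y / sqrt(mean(y^2))
}

#' Stereotyped eye-blink waveform
#'
#' A biphasic template: smooth (raised-cosine) upstroke to the peak followed
#' by a slower raised-cosine downstroke, so the time-reversed downstroke is
#' perfectly correlated with the upstroke.
#'
#' @param sampling_rate sampling rate in Hz.
#' @param amplitude peak amplitude (same units as the signal, e.g. uV).
#' @param up_s,down_s upstroke / downstroke durations in seconds; total
#'   duration must be at least 50 ms.
#' @return numeric vector with the template samples.
#' @export
blink_template <- function(sampling_rate, amplitude = 100,
                           up_s = 0.12, down_s = 0.18) {
  if (up_s + down_s < 0.05) stop("template duration must be >= 50 ms", call. = FALSE)
  n_up <- max(2L, round(up_s * sampling_rate))
  n_down <- max(2L, round(down_s * sampling_rate))
  up <- (1 - cos(pi * seq(0, 1, length.out = n_up))) / 2
  down <- (1 + cos(pi * seq(0, 1, length.out = n_down + 1)[-1])) / 2
  amplitude * c(up, down)
}

#' Inject blink waveforms into a single-channel signal
#'
#' Adds the template at each onset. Onsets whose templates would overlap are
#' rejected (they are not merged).
#'
#' @param signal numeric vector (one channel).
#' @param sampling_rate sampling rate in Hz.
#' @param onsets_s numeric vector of onset times in seconds.
#' @param template waveform from [blink_template()].
#' @return the modified signal; the ground-truth onsets are the input onsets.
#' @export
inject_blinks <- function(signal, sampling_rate, onsets_s, template) {
  if (!length(onsets_s)) return(signal)
  dur_s <- length(template) / sampling_rate
  onsets_s <- sort(onsets_s)
  if (any(diff(onsets_s) < dur_s)) {
    stop("blink templates would overlap; onsets are not merged", call. = FALSE)
  }
  n <- length(signal)
  for (t0 in onsets_s) {
    i0 <- round(t0 * sampling_rate) + 1L
    i1 <- i0 + length(template) - 1L
    if (i0 < 1 || i1 > n) stop("blink onset outside the signal", call. = FALSE)
    signal[i0:i1] <- signal[i0:i1] + template
  }
  signal
}

## Per-electrode alpha RMS amplitude (uV) for one subject in one state.
## Encodes: posterior dominance (frontal:temporal:parietal:occipital =
## 1 : 1.2 : 1.6 : 2.0), eyes-open alpha at 40% of eyes-closed, the
## fronto-temporally concentrated patient reduction, the lateralized
## reduction on the seizure hemisphere and the profile's alpha_scale.
## A focus in the dominant hemisphere (left for right-handed subjects)
## disrupts alpha more globally: half the lateral reduction spreads to the
## contralateral hemisphere, so dominant-side foci are detectably lower
## overall while the ipsilateral asymmetry is preserved.
alpha_amplitude <- function(profile, config, electrode, state) {
  region <- ELECTRODE_REGION[[electrode]]
  hemi <- ELECTRODE_HEMISPHERE[[electrode]]
  base <- 5 * c(frontal = 1, temporal = 1.2, parietal = 1.6, occipital = 2.0)[[region]]
  if (state == "EO") base <- base * 0.4
  if (profile$group == "patient") {
    red <- if (region %in% c("frontal", "temporal")) config$effect_size else 0.4 * config$effect_size
    base <- base * (1 - red)
    if (profile$seizure_hemisphere != "none") {
      dominant <- if (profile$handedness == "right") "left" else "right"
      if (hemi == profile$seizure_hemisphere) {
        base <- base * (1 - config$lateral_effect)
      } else if (profile$seizure_hemisphere == dominant) {
        base <- base * (1 - config$lateral_effect / 2)
      }
    }
  }
  base * profile$alpha_scale[region, hemi]
}

#' Synthesize one subject's annotated multichannel recording
#'
#' Each referential channel is 1/f background (SD 10 uV) plus a shared
#' common-mode component (5 uV, cancelled by the bipolar derivation) plus an
#' independent band-limited alpha oscillation whose amplitude encodes the
#' posterior-dominance gradient, the eyes-closed amplification and the
#' profile's group/hemisphere effects. Eyes-open segments receive injected
#' blink waveforms on the most anterior channels (Fp1/Fp2, else F7/F8) at the
#' profile's blink rate, with ground-truth onsets recorded. Segments
#' alternate EC/EO starting with EC.
#'
#' @param profile a [subject_profile()].
#' @param config a [cohort_config()].
#' @param seed integer seed for this subject's signals.
#' @return an `eeg_recording`: list with `subject`, `sampling_rate`,
#'   `channel_labels`, `data` (channels x samples, uV), `annotations`
#'   (onset_s, duration_s, state) and `blink_onsets`.
#' @export
synthesize_subject <- function(profile, config, seed = config$seed) {
  stopifnot(inherits(profile, "subject_profile"), inherits(config, "cohort_config"))
  set.seed(seed)
  fs <- config$sampling_rate
  seg_n <- round(config$segment_s * fs)
  states <- character(0)
  ec_left <- config$n_ec; eo_left <- config$n_eo
  while (ec_left > 0 || eo_left > 0) {
    if (ec_left > 0) { states <- c(states, "EC"); ec_left <- ec_left - 1 }
    if (eo_left > 0) { states <- c(states, "EO"); eo_left <- eo_left - 1 }
  }
  n_seg <- length(states)
  channels <- config$channel_set
  data <- matrix(0, length(channels), n_seg * seg_n,
                 dimnames = list(channels, NULL))
  blink_chans <- intersect(c("Fp1", "Fp2"), channels)
  if (!length(blink_chans)) blink_chans <- intersect(c("F7", "F8"), channels)
  tpl <- blink_template(fs)
  tpl_s <- length(tpl) / fs
  blink_onsets <- numeric(0)
  for (s in seq_len(n_seg)) {
    idx <- ((s - 1) * seg_n + 1):(s * seg_n)
    common <- 5 * generate_background(config$segment_s, fs, 1, config$noise_exponent)[1, ]
    for (ch in channels) {
      bg <- 10 * generate_background(config$segment_s, fs, 1, config$noise_exponent)[1, ]
      amp <- alpha_amplitude(profile, config, ch, states[s])
      alpha <- generate_alpha_component(config$segment_s, fs,
                                        config$alpha_freq, config$alpha_bw, amp)
      data[ch, idx] <- bg + common + alpha
    }
    if (states[s] == "EO" && profile$blink_rate > 0 && length(blink_chans)) {
      n_blinks <- rpois(1, profile$blink_rate * config$segment_s / 60)
      onsets <- draw_spaced_onsets(n_blinks, config$segment_s - tpl_s, tpl_s + 0.1)
      if (length(onsets)) {
        for (ch in blink_chans) {
          data[ch, idx] <- inject_blinks(data[ch, idx], fs, onsets, tpl)
        }
        blink_onsets <- c(blink_onsets, (s - 1) * config$segment_s + onsets)
      }
    }
  }
  annotations <- data.frame(
    onset_s = (seq_len(n_seg) - 1) * config$segment_s,
    duration_s = config$segment_s,
    state = states,
    stringsAsFactors = FALSE
  )
  new_recording(profile, fs, channels, data, annotations, blink_onsets)
}

## Uniform onsets with a minimum separation (rejection sampling; gives up on
## onsets that cannot be placed rather than merging them).
draw_spaced_onsets <- function(n, max_s, min_gap) {
  onsets <- numeric(0)
  tries <- 0
  while (length(onsets) < n && tries < 200 * max(n, 1)) {
    cand <- runif(1, 0, max_s)
    if (!length(onsets) || min(abs(onsets - cand)) >= min_gap) {
      onsets <- c(onsets, cand)
    }
    tries <- tries + 1
  }
  sort(onsets)
}

new_recording <- function(subject, sampling_rate, channel_labels, data,
                          annotations, blink_onsets = numeric(0)) {
  stopifnot(nrow(data) == length(channel_labels))
  validate_annotations(annotations, ncol(data) / sampling_rate)
  structure(
    list(subject = subject, sampling_rate = sampling_rate,
         channel_labels = channel_labels, data = data,
         annotations = annotations, blink_onsets = blink_onsets),
    class = "eeg_recording"
  )
}

validate_annotations <- function(ann, total_s) {
  stopifnot(is.data.frame(ann),
            all(c("onset_s", "duration_s", "state") %in% names(ann)))
  if (!all(ann$state %in% c("EC", "EO"))) {
    stop("annotation states must be EC or EO", call. = FALSE)
  }
  ord <- order(ann$onset_s)
  ends <- ann$onset_s[ord] + ann$duration_s[ord]
  if (any(ann$onset_s < 0) || any(ends > total_s + 1e-9)) {
    stop("annotations extend outside the recording", call. = FALSE)
  }
  if (nrow(ann) > 1 && any(ends[-length(ends)] > ann$onset_s[ord][-1] + 1e-9)) {
    stop("annotations overlap", call. = FALSE)
  }
  invisible(ann)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s (%s): %d channels x %d samples @ %g Hz, %d segments\n",
              x$subject$subject_id, x$subject$group, nrow(x$data), ncol(x$data),
              x$sampling_rate, nrow(x$annotations)))
  invisible(x)
}

#' Deterministic subject metadata for a cohort configuration
#'
#' Builds the subject table (and profiles) implied by a [cohort_config()]
#' without synthesizing any signals. Healthy ages follow a bimodal
#' young (20-35) / old (59-77) split; patient ages are uniform on 18-66.
#' Lateralized patients alternate left/right seizure hemispheres; a
#' `left_hand_fraction` of patients is simulated left-handed; patients
#' receive an anti-seizure-medication flag (levetiracetam or lamotrigine)
#' with probability 0.9.
#'
#' @param config a [cohort_config()].
#' @return data.frame with columns subject_id, group, cohort_role, age_years,
#'   handedness, seizure_hemisphere, blink_rate, medications; the profiles
#'   are attached as the `profiles` attribute.
#' @export
cohort_metadata <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  profiles <- list()
  rows <- list()
  i <- 0
  for (role in names(config$n_per_group)) {
    for (j in seq_len(config$n_per_group[[role]])) {
      i <- i + 1
      group <- if (role == "lateralized") "patient" else role
      id <- sprintf("%s%03d", toupper(substr(role, 1, 1)), i)
      if (group == "healthy" || group == "comparison") {
        age <- if (runif(1) < 2 / 3) runif(1, 20, 35) else runif(1, 59, 77)
      } else {
        age <- runif(1, 18, 66)
      }
      hemi <- if (role == "lateralized") c("left", "right")[1 + j %% 2] else "none"
      hand <- if (group == "patient" && runif(1) < config$left_hand_fraction) "left" else "right"
      meds <- if (group == "patient" && runif(1) < 0.9) {
        sample(c("levetiracetam", "lamotrigine"), 1)
      } else character()
      profiles[[id]] <- subject_profile(
        id, group = group, age_years = round(age, 1), handedness = hand,
        seizure_hemisphere = hemi, blink_rate = config$blink_rate,
        medications = meds
      )
      rows[[id]] <- data.frame(
        subject_id = id, group = group, cohort_role = role,
        age_years = round(age, 1), handedness = hand,
        seizure_hemisphere = hemi, blink_rate = config$blink_rate,
        medications = paste(meds, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  md <- do.call(rbind, rows)
  rownames(md) <- NULL
  attr(md, "profiles") <- profiles
  md
}

## Per-subject signal seed derived from the cohort seed; kept below 2^31.
subject_seed <- function(config_seed, index) {
  (as.numeric(config_seed) * 1009 + index * 7919) %% 2147483647
}

#' Generate a full synthetic cohort
#'
#' Deterministic given the config seed: metadata, profiles and every
#' subject's signals are reproduced bit-identically on re-run.
#'
#' @param config a [cohort_config()].
#' @return list of `eeg_recording` objects, named by subject id, with the
#'   metadata table attached as the `metadata` attribute.
#' @export
generate_cohort <- function(config) {
  md <- cohort_metadata(config)
  profiles <- attr(md, "profiles")
  recs <- vector("list", length(profiles))
  names(recs) <- names(profiles)
  for (i in seq_along(profiles)) {
    recs[[i]] <- synthesize_subject(profiles[[i]], config,
                                    seed = subject_seed(config$seed, i))
  }
  attr(recs, "metadata") <- md
  recs
}
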