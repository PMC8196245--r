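## Shared fixtures, built lazily and cached for the whole test run. All
## signal fixtures are generated at 128 Hz to keep the suite fast; the
## generator itself is rate-agnostic.

.fixture_env <- new.env(parent = emptyenv())

REQUIRED_ELECTRODES <- alphanorm:::REQUIRED_ELECTRODES

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

## Small mixed cohort with a strong fronto-temporal patient effect and a
## lateralized subgroup; EC and EO features.
mini_config <- function() {
  cohort_config(
    n_per_group = c(healthy = 10, patient = 5, lateralized = 4),
    n_ec = 2, n_eo = 1, segment_s = 60, sampling_rate = 128,
    effect_size = 0.5, lateral_effect = 0.4, left_hand_fraction = 0,
    seed = 404
  )
}

mini_features <- function() {
  fixture("mini_features", function() {
    cohort_feature_table(mini_config(), states = c("EC", "EO"))
  })
}

mini_metadata <- function() attr(mini_features(), "metadata")

## One healthy recording with EC and EO segments (for windowing/blink tests).
mini_recording <- function() {
  fixture("mini_recording", function() {
    cfg <- cohort_config(n_per_group = c(healthy = 1), n_ec = 2, n_eo = 2,
                         segment_s = 60, sampling_rate = 128, seed = 11)
    md <- cohort_metadata(cfg)
    synthesize_subject(attr(md, "profiles")[[1]], cfg, seed = 17)
  })
}

## Build a tidy feature table from a windows x 16 matrix of log-fractions
## (canonical channel-major, band-minor order). Used to drive the normative
## model with hand-chosen reference samples.
table_from_matrix <- function(mat, subject_ids = NULL, state = "EC") {
  m <- default_montage()
  bands <- c("low_alpha", "high_alpha")
  feat_chan <- rep(m$channel, each = 2)
  feat_band <- rep(bands, times = 8)
  n <- nrow(mat)
  if (is.null(subject_ids)) subject_ids <- rep("S1", n)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(subject_id = subject_ids[i], window_index = i - 1L,
               state = state, channel = feat_chan, band = feat_band,
               log_fraction = as.numeric(mat[i, ]), stringsAsFactors = FALSE)
  }))
}

## Normative model whose every feature has the same reference sample.
model_from_reference <- function(ref) {
  table_from_matrix(matrix(rep(ref, 16), ncol = 16)) |> fit_normative()
}
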