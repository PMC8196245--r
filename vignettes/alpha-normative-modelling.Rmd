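---
title: "Normative modelling of eyes-closed alpha power in scalp EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modelling of eyes-closed alpha power in scalp EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The alpha rhythm — the 8–13 Hz oscillation that dominates awake, eyes-closed
EEG over posterior scalp — is one of the most robust electrophysiological
signatures of normal adult brain function. It is posteriorly dominant,
attenuates when the eyes open, and is disrupted in a range of neurological
conditions, including focal epilepsy, where the fraction of spectral power
in the alpha band is reduced even in recordings that expert reviewers
classify as normal.

`alphanorm` implements a complete, testable pipeline for quantifying such
disruptions: it reduces a multichannel recording to sixteen alpha-power
fraction features per 10-second eyes-closed window, characterizes a healthy
reference population by the empirical distribution of each feature, and
scores new windows — and subjects — by a *probability-of-normality*, the
likelihood that their features come from the reference population. Because
clinical recordings cannot be redistributed, the package ships a synthetic
cohort generator that emulates the relevant structure of real eyes-closed /
eyes-open EEG, so that every stage of the pipeline is exercised end to end
by reproducible simulations.

## The feature model

For each subject, annotated eyes-closed segments are:

1. **Band-pass filtered** 1–45 Hz with an 8th-order Butterworth design
   applied forward–backward (zero-phase).
2. **Re-referenced** to an eight-channel bipolar montage — one
   anterior–posterior derivation per major region and hemisphere:
   F7–F3, T7–C3, P7–P3, O1–P3 (left) and F8–F4, T8–C4, P8–P4, O2–P4
   (right). Bipolar derivation cancels activity common to neighbouring
   electrodes (reference drift, far-field sources).
3. **Cut into windows**: each channel is z-scored over its parent segment
   (not per window), then split into consecutive non-overlapping 10-s
   windows; a trailing remainder shorter than 10 s is discarded, so all
   windows are identically sized. Eight 60-s segments therefore yield
   exactly 48 windows.
4. **Summarised spectrally**: the multitaper power spectral density of
   each window (Slepian tapers, time–bandwidth NW = 4, K = 7 tapers,
   unity weighting) is integrated over the low-alpha (7.5–10.5 Hz) and
   high-alpha (10.5–13.5 Hz) bands and divided by the 0.5–40 Hz wide-band
   power. The two disjoint sub-bands let a model see alpha *slowing*
   (relative shift into low-alpha) as well as overall reduction. Each
   window yields 16 features — 8 channels × 2 bands — stored as log
   fractions.

Normalizing by wide-band power makes every feature exactly invariant to a
rescaling of the input signal, which removes subject- and
acquisition-specific differences in total signal power; the z-scoring step
makes this invariance hold segment by segment. The band edges are
integrated exactly (the PSD is linearly interpolated at 7.5, 10.5, 13.5,
0.5 and 40 Hz), so the two alpha fractions tile the band with no double
counting and their sum can never exceed 1.

## The normative model

Let $x_k$, $k = 1, \dots, 16$, be the log feature values of one window and
$F_k$ the empirical CDF of feature $k$ pooled over all reference
(healthy) windows. The per-feature probability-of-normality of a new value
is $F_k(x_k')$: values in the lower tail of the healthy distribution score
near 0, values near the upper support score near 1. The combined
window-level score is the geometric mean across a feature subset $S$,

$$P(x' \in \text{Normal}) \;=\; \Big(\prod_{k \in S} F_k(x_k')\Big)^{1/|S|}
 \;=\; \exp\Big(\tfrac{1}{|S|}\sum_{k \in S} \log F_k(x_k')\Big),$$

computed in the log domain for numerical stability. Treating a subject's
window scores $Y_{i,n}$ as independent Bernoulli observations with unknown
success probability $\pi_i$, the maximum-likelihood estimate of the
subject-level probability-of-normality is the arithmetic mean
$\hat\pi_i = \frac{1}{N_i}\sum_n Y_{i,n}$; `subject_probability()` computes
exactly that, and the test suite verifies the maximizer by grid search.

Two numerical choices matter here:

* **ECDF plotting position.** A raw ECDF returns 0 for any value below the
  reference minimum, and a single zero annihilates the geometric mean.
  `ecdf_eval()` therefore uses the Hazen (midrank) plotting position
  $F(x) = (\#\{r < x\} + 0.5\,\#\{r = x\})/n$, clamped to
  $[1/(2n),\, 1 - 1/(2n)]$. Ties receive half weight, consistent with the
  midrank convention. Clamping can be disabled for closed-form checks.
* **Feature subsets.** The combining exponent generalizes to $1/|S|$ for
  the named subsets `"frontotemporal"` (F7–F3, T7–C3, F8–F4, T8–C4, both
  bands; 8 features) and `"frontotemporal_high"` (those channels, high
  band only; 4 features).

Group-level contrasts use the first-order Wasserstein distance between the
two groups' pooled per-feature samples — the area between their empirical
CDFs — computed exactly from the quantile functions.

## The evaluation framework

`make_splits()` draws repeated random train/test splits: each repetition
selects a fresh random reference sample of healthy subjects (96 by
default); the remaining healthy subjects and the patients form a
class-balanced test set, disjoint from the reference. This *repeated
random subsampling* design (rather than a partition into folds) matches
how the reference-resampling evaluation is defined; the interface calls
the iterations "repetitions". Per repetition, `run_task()` fits the
normative model on the reference sample, scores every test subject, and
computes ROC metrics with patients as the positive class — a *low*
probability-of-normality indicates a positive. The hemisphere task scores
right-handed lateralized patients only (left-hemisphere focus = positive)
against the same healthy-fitted model.

AUC is computed by trapezoid over the threshold sweep and equals the
Mann–Whitney statistic with ties counted one half (verified against an
$O(n^2)$ oracle). The operating threshold is chosen by the ROC convex-hull
method: among the vertices of the upper convex hull, the one maximizing
TPR − FPR (iso-performance slope 1, appropriate for the balanced test
design; the slope is exposed as a cost ratio). Precision, recall and F1
are reported as percentages at that threshold.

Group statistics follow the same contract as the rest of the pipeline:
`rank_sum_test()` uses exact enumeration of rank assignments for
$n_1 + n_2 \le 20$ (ties handled exactly via midranks) and a tie- and
continuity-corrected normal approximation otherwise; `tukey_hsd()`
implements Tukey–Kramer pairwise comparisons via the studentized-range
distribution and also returns per-group comparison intervals
$\bar y_g \pm \tfrac{q}{2}\sqrt{\mathrm{MSE}/n_g}$, whose non-overlap is
equivalent to pairwise significance in balanced designs (approximate
otherwise). `stratify()` turns metadata predicates (age bands, handedness,
medication flags, seizure hemisphere) into named subject groups for these
comparisons.

## The synthetic cohort generator

The generator's defaults fix the study conditions; they were chosen once,
from the qualitative structure the pipeline must be able to recover, and
are not tuned per experiment:

* **Background**: independent per-electrode 1/f-type noise (spectral slope
  1 over 0.5–40 Hz, flat below 0.5 Hz), SD 10 µV, plus a 5 µV common-mode
  component shared across electrodes in each segment. The common mode
  cancels in the bipolar derivation, making that step non-trivial to test.
* **Alpha**: a band-limited Gaussian process (Gaussian spectral envelope,
  centre 10 Hz, bandwidth 2 Hz) rather than a sinusoid, so multitaper
  estimates have realistic variance — with a pure tone, the
  probability-integral-transform calibration checks would be degenerate.
  Each electrode receives an independent realization; amplitudes follow
  the posterior-dominance gradient frontal : temporal : parietal :
  occipital = 1 : 1.2 : 1.6 : 2.0 (frontal eyes-closed RMS 5 µV), with
  eyes-open alpha at 40% of eyes-closed.
* **Group effects**: patients' alpha amplitude is reduced by
  `effect_size`, concentrated fronto-temporally (parieto-occipital
  electrodes receive 0.4× the fractional reduction). Lateralized patients
  additionally lose `lateral_effect` on the seizure hemisphere; a focus in
  the *dominant* hemisphere (left, for right-handed subjects) spreads half
  of that reduction contralaterally. The spread reflects the clinical
  observation that dominant-hemisphere foci disrupt normal activity more
  globally, and it is what makes the hemisphere task solvable from the
  symmetric 16-feature score: with a purely ipsilateral reduction, left-
  and right-focus subjects are mirror images and the combined probability
  cannot separate them.
* **Blinks**: eyes-open segments receive additive biphasic templates
  (raised-cosine upstroke 0.12 s to 100 µV, slower raised-cosine
  downstroke 0.18 s) at the profile's blink rate, with ground-truth onsets
  recorded and overlapping placements rejected.
* **Metadata**: healthy ages follow the bimodal young (20–35) / old
  (59–77) split typical of normative EEG cohorts; patient ages are
  uniform 18–66; lateralized patients alternate left/right foci; a
  configurable fraction of patients is left-handed; patients carry an
  anti-seizure-medication flag usable by `stratify()`.

Everything is deterministic given the config seed: per-subject signal
seeds are derived arithmetically, so cohorts regenerate bit-identically
and individual subjects can be re-synthesized without the rest of the
cohort.

**What the generator does *not* emulate** — and hence what passing tests
do and do not show. Real EEG has strong inter-individual variability in
alpha power and peak frequency, age-dependent slowing, non-stationary
arousal drift, epileptiform transients (absent by definition in this
setting), muscle and electrode artefacts, and volume-conduction
correlation structure far richer than one shared common mode. Subjects
here are exchangeable within group: there is no per-subject random effect
by default, which keeps held-out windows exactly calibrated under the
reference distribution (the PIT checks test the scoring machinery, not
robustness to population heterogeneity). Consequently, classification
AUCs on synthetic cohorts characterize *parameter recovery* — that the
pipeline detects the structure the generator injected — and say nothing
about clinical effect sizes.

## Eye-blink counting

Blink rate in eyes-open segments is used as a surrogate for arousal
differences between groups. The detector works on the mean of the most
anterior available referential channels (Fp1/Fp2, else F7/F8), low-passed
at 8 Hz — blinks are slow events, and smoothing prevents alpha and
high-frequency background from corrupting the stroke correlation. Level 1
("all potential") counts maximal runs above mean + 1.5 SD lasting longer
than 50 ms. Level 2 ("specific") requires the upstroke (event start to
absolute peak) and the time-reversed, linearly resampled downstroke to
correlate with $R^2 > 0.90$. Events are extended from the suprathreshold
run down to 15% of their peak excursion (capped at 0.2 s per side, so
neighbouring events never merge) and linearly detrended before the
correlation, which removes the slow background drift that would otherwise
dominate the stroke shapes. The 8 Hz corner, the 15% extension level and
the 0.2 s cap are the detector's own design constants, chosen from the
template geometry, and are exposed as arguments.

## Numerical and design notes

* **Filtering.** A 16-pole Butterworth band-pass expressed as a single
  transfer function is numerically unstable at EEG sampling rates (the
  passband gain errs by ~15%). The filter is therefore applied as a
  cascade of an 8th-order high-pass at 1 Hz and an 8th-order low-pass at
  45 Hz, each forward–backward. Measured response: gain 1.000 at 10 Hz,
  −46 dB at 60 Hz, −63 dB at 0.1 Hz. Note the deliberate band mismatch
  inherited from the analysis design: spectra are normalized over
  0.5–40 Hz while the filter passes 1–45 Hz, so the 0.5–1 Hz part of the
  normalization integral is attenuated signal, not raw signal. The
  wide-band definition is kept as stated and the inconsistency flagged
  here rather than silently resolved.
* **Multitaper parameters.** NW = 4 with K = 7 tapers is a standard
  choice giving ±0.4 Hz spectral concentration on 10-s windows; both are
  configurable. Eigenspectra are unity-weighted. Tapers come from the
  symmetric tridiagonal formulation and are cached per window length.
* **Windowing edge cases.** Segments shorter than one window contribute
  zero windows (logged, not an error); an empty state selection returns
  an empty list. Z-scoring is idempotent at segment level to 1e-10.
* **Ties and degenerate inputs.** ECDF ties use midranks; all-equal
  scores give AUC 0.5; zero predicted positives make precision NaN with a
  warning; a zero wide-band power raises an error rather than returning
  NaN fractions.
* **EDF I/O.** Recordings round-trip through 16-bit EDF with per-channel
  physical scaling, so the quantization error is bounded by the channel
  range divided by 65535. Channel labels are normalized case-insensitively,
  reference suffixes are stripped, and legacy 10–20 names (T3/T4/T5/T6)
  map onto their 10–10 equivalents.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the full pipeline at
desktop scale, as the package's own choice of simulation size: a 96-subject
healthy reference population (8 × 60 s eyes-closed segments each, 128 Hz)
for calibration and structural checks; 50 + 20 + 20 subject cohorts for
the null and strong-effect classification experiments; 12-subject patient
cohorts along the effect-size grid {0, 0.2, 0.4, 0.6}; ten 20-subject
cohorts for the spatial-localization check; and five minutes of eyes-open
signal at 250 Hz for the blink counter. Sampling at 128 Hz for the large
cohorts (rather than the 250–256 Hz of clinical hardware) leaves every
band edge far below Nyquist and does not change any feature definition.

## Known limitations

* The independence assumption behind the geometric-mean combination is
  knowingly false — neighbouring derivations share electrodes and both
  bands share the wide-band denominator — but it is the model's stated
  design; no copula or multivariate alternative is provided.
* The normative model is purely empirical: no parametric density, no
  covariate adjustment (age enters only through `stratify()` contrasts).
* The hemisphere task inherits the generator's dominant-hemisphere
  assumption; on real data the equivalent association is an empirical
  finding, not a mechanism the pipeline can verify.
* EDF support covers continuous 16-bit recordings with equal sampling
  rates across channels; EDF+ annotation signals are not parsed (the
  sidecar TSV carries the annotations instead).
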