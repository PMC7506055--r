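---
title: "Continuous-tracking oculomotor assessment: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-tracking oculomotor assessment: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazescreen)
```

## The measurement problem

Clinical oculomotor testing usually asks a patient to fixate and then make
discrete, instructed saccades. `gazescreen` implements the alternative
continuous-tracking paradigm: the subject follows a small Gaussian blob
moving in a random walk for 20-second trials, and every analysis quantity —
smooth-pursuit quality, saccade dynamics, directional saccade statistics —
is extracted from the single continuous binocular recording. Because a
random walk with independent increments carries no temporal autocorrelation,
the subject cannot anticipate the target, and the cross-correlation between
stimulus and eye velocity isolates the visuomotor response.

The package covers the full chain: stimulus generation, gaze I/O, saccade
detection, main-sequence fitting, spatio-temporal feature extraction,
robust normative scoring, directional profiling, and an unsupervised
screening pipeline. A synthetic-observer simulator with parametric
impairments provides ground truth for every stage; no patient data ship
with the package.

## Stimulus model

`generate_random_walk()` draws i.i.d. Gaussian positional increments per
frame (default SD 0.07 deg/frame at 60 Hz, giving a median target speed
near 5 deg/s — the exact speed statistics of the original protocol are not
published, so this is a configurable package default chosen to keep the
target comfortably pursuable). Independent increments are what guarantee
the absence of serial autocorrelation in the target velocity, which the
cross-correlogram features rely on. The walk is confined to the display
(default half-extents 15.4 x 9.6 degrees, a 24-inch widescreen at 60 cm) by
reflection at the edges; reflection, unlike clamping, leaves increments
unbiased near the boundary. The boundary rule is a package choice — any
rule that stays in bounds without biasing increments would do.

The saccadic condition (`add_saccadic_displacements()`) adds a jump to a
uniformly random in-bounds location every 2 s. Jumps happen at interior
multiples of the interval only — t = 2, 4, ..., 18 s in a 20-s trial, nine
events — since a jump at trial onset or offset would be unmeasurable.

The target itself is a Gaussian luminance blob with a full width at half
maximum of 0.83 degrees (about a Goldmann size-III perimetric stimulus),
shown at two contrast levels on a ~140 cd/m^2 grey background with peak
luminances of ~385 (high) and ~160 (low) cd/m^2. These luminances are
stored as configured constants rather than derived from a contrast formula:
neither a Weber nor a Michelson definition reproduces the nominal 50%/10%
contrast labels from those luminance pairs, so the printed values are
treated as the specification. `measure_fwhm()` measures the width
numerically from the rendered profile rather than echoing the parameter.

The default protocol (`build_protocol()`) is 12 trials of 20 s — six per
condition, four minutes of tracking in total. The allocation of contrast
levels across trials is not documented in the source protocol; the default
schedule assigns three high- and three low-contrast trials per condition,
interleaved.

## Saccade detection

Saccades are found per eye with an adaptive acceleration threshold
(`detect_saccades()`): at every frame the threshold equals K = 3.4 times
the sample SD of the acceleration magnitude over the preceding 60 samples
(1 s at 60 Hz). A data-driven threshold adapts to each recording's noise
level, which matters at 60 Hz where fixed velocity criteria are unreliable;
it also makes detection invariant under rescaling of the position traces.
During the first second, where no full trailing window exists yet, the SD
of the first complete window is used.

Velocity and acceleration come from central differences (one-sided at the
endpoints), deliberately without any temporal filtering of the velocity
signal: at 60 Hz a low-pass filter would smear the 2-4-sample saccades the
detector is looking for. The 2-D acceleration is scalarised as the vector
magnitude by default (a per-axis OR combination is available via
`detector_config(per_axis = TRUE)`).

Supra-threshold runs separated by at most 1 frame are merged and runs
shorter than 2 frames (~33 ms) are discarded — single-frame events at
60 Hz are indistinguishable from noise. Each surviving run is parameterised
by amplitude (Euclidean start-to-end displacement, endpoints taken one
frame outside the run), peak velocity (maximum speed inside the run) and
direction (angle of the displacement vector, 0 = rightward, 90 = upward).
Saccades overlapping invalid or interpolated frames are flagged and can be
excluded from dynamics statistics.

Because the stencil of central differences spans two frames on either
side, a detected onset systematically precedes the first frame of actual
motion by up to two frames; tests that match detections to simulator
ground truth therefore use a small frame tolerance for event identity.

A practical consequence of the trailing-window design is that the
threshold is strongly elevated for about a second after each large
saccade, so closely spaced small saccades can be missed; this is inherent
to the algorithm, not an implementation artefact.

## Main sequence

`fit_main_sequence()` fits the saturating exponential
V(A) = V_max (1 − exp(−A / A_63)) by separable least squares (the model is linear in V_max given A_63, so the fit profiles a 1-D criterion over A_63 — immune to the singular-gradient failures of joint nonlinear search on flat or saturated data);
this is the standard parameterisation of the amplitude–peak-velocity
relationship ("main sequence"), with V_max the velocity ceiling and A_63
the amplitude at 63% of it. A log-log power law is available behind
`form = "power"`. Prediction bands (`prediction_interval()`) assume
Gaussian residuals on the velocity scale with amplitude-independent
variance by default (`heteroscedastic = TRUE` scales the residual SD with
the fitted value); group comparisons use the geometric criterion of
`bands_overlap()` — two groups are indistinguishable when their 95%
prediction bands intersect at every grid amplitude — because the source
analysis reports overlap visually rather than via a named test.

## Spatio-temporal tracking features

Ten features are computed per axis (horizontal/vertical), per condition
(smooth/saccadic) and per eye, giving the 80-entry vector of
`extract_stp_vector()` (10 x 2 x 2 x 2):

| id | feature | units |
|----|---------|-------|
| F1 | tracking lag: mean of a Gaussian fitted to the eye-stimulus velocity cross-correlogram peak | s |
| F2 | temporal uncertainty: SD of that Gaussian | s |
| F3 | error spread: SD of the positional eye-stimulus deviation | deg |
| F4 | dissimilarity: 1 − cosine similarity of the (mean-centred) coordinate arrays | — |
| F5 | peak correlogram height | — |
| F6 | positional bias: mean signed error | deg |
| F7 | velocity gain: regression slope of eye on stimulus velocity, aligned at the correlogram peak lag | — |
| F8 | root-mean-square positional error | deg |
| F9 | on-target fraction: share of frames with absolute error < 2 deg | — |
| F10 | error persistence: lag-1 autocorrelation of the positional error | — |

F1–F4 are the named features of the published method; the identities of
the remaining six are described only in an unavailable supplement, so
F5–F10 are an explicit package-defined registry that preserves the
10 x 2 x 2 x 2 structure and can be replaced without touching the rest of
the pipeline.

Three numerical choices deserve mention. First, the correlogram readout:
the Gaussian is fitted in closed form by a log-quadratic (Caruana) fit to
the contiguous lags above half peak; if fewer than three such points exist
or the quadratic is not concave (e.g. the near-delta correlogram of
noiseless tracking), the readout falls back to the discrete argmax and the
Gaussian-equivalent half width, flagged as such. Second, the velocity-gain
regression aligns the eye trace at the correlogram peak lag before
computing the slope — with an autocorrelation-free stimulus, a lag-0
regression would read any latency as near-zero gain, conflating two
distinct impairments. Third, features are computed per trial and
aggregated across each condition's trials by the median, which tolerates a
single corrupted trial; whether the original analysis aggregated per trial
or concatenated trials is unstated, and the median is this package's
choice. Cosine similarity is computed on mean-centred arrays so that a
static offset loads on F6 (bias) rather than saturating F4.

Saccadic-condition traces are used whole: the method is a
continuous-tracking assessment, and excising saccades would discard the
catch-up behaviour the saccadic condition exists to elicit.

## Directional saccade statistics

`bin_directions()` bins saccade directions into 12 sectors of 30 degrees
centred on 0, 30, ..., 330 (the bin count is an acknowledged arbitrary
choice in the source method and is configurable); a direction exactly on
an edge goes to the counterclockwise bin. Frequency shares are normalised
per eye, so a unilateral deficit appears as inter-eye asymmetry rather
than being averaged away. Within each bin, amplitude and peak velocity are
stratified at their quartiles and summarised by the within-quartile mean,
so each quartile carries its own normative boundaries downstream; bins
with fewer than four saccades are marked sparse and propagate as missing,
never as zero.

## Normative scoring

`build_reference()` stores the per-feature median (MED) and median
absolute deviation (MAD) over a control group, optionally age-filtered
(e.g. a >= 50-years control subgroup for comparison with older patient
groups). Scoring uses the modified z-score

z = (x − MED) / (1.486 · MAD),

with 1.486 the constant that makes the MAD a consistent estimator of the
Gaussian SD; a feature is abnormal when |z| >= 2. The source text is
ambiguous about whether MAD denotes the median or the mean absolute
deviation; the 1.486 constant is only consistent with the median-based
estimator, which is therefore the default, with `scale = "mean_abs"`
exposed for the alternative reading. Group-level comparisons use one-tailed
Welch t-tests (unequal variances, Welch–Satterthwaite df) at alpha = 0.05
with no multiple-testing correction by default (a Benjamini–Hochberg
option exists); the tail direction per feature is the caller's choice,
with "impairment-increasing" (patients exceed controls on lag,
uncertainty, spread, dissimilarity) the natural preset.

## Screening pipeline

`screen_cohort()` chains per-feature standardised PCA (retaining the
smallest component set explaining >= 95% of variance), a 2-D t-SNE
embedding of the retained components (perplexity 10, suited to cohorts of
~70 subjects), elbow-method selection of k on the within-cluster sum of
squares, and k-means (k-means++ seeding, Lloyd iterations, best of 10
restarts). Whether features should be column-standardised before the PCA
is not documented for the original analysis; standardisation is the
default here because the 80 features mix units (seconds, degrees,
dimensionless), and `standardize = FALSE` preserves the raw-scale
behaviour. The elbow is formalised as the point of maximum distance from
the chord joining the normalised WSS curve's endpoints; only a degenerate
curve (WSS already ~zero at the smallest candidate k, as for coincident
points) is declared elbow-free. Because the WSS of structureless data
still decays roughly as 1/k, no WSS-based rule can attest the *absence*
of cluster structure — the elbow choice is a heuristic, not a test.
Missing features are median-imputed (with a recorded count) or
handled by complete-case analysis, at the caller's choice. The entire
pipeline is reproducible from one seed.

## The synthetic observer

`simulate_observer()` generates binocular responses: per frame, eye
velocity is pursuit_gain times the stimulus velocity delayed by the
latency (capped at a pursuit speed limit of 25 deg/s, so target jumps must
be corrected saccadically), plus Gaussian drift noise. When the cyclopean
positional error exceeds the trigger threshold, a catch-up saccade is
emitted: each eye corrects its own error with amplitude = error x saccade
gain, a raised-cosine velocity profile, and a peak velocity drawn from the
observer's main sequence (duration = 2A / V_peak). The presets encode
clinical phenomenology directionally: `ms_ino_like` has hypermetric
saccades (gain 1.3) and a left-eye adduction deficit (nasal saccades
executed with probability 0.5; an omitted saccade is replaced by a slow
sub-threshold glissade, the slowed-adduction signature of internuclear
ophthalmoplegia); `pd_like` has
longer latency (220 ms), reduced pursuit gain (0.7), hypometric saccades
(gain 0.7) and 70% suppression of vertical catch-up saccades. These
parameter values are package-owned: the source describes the phenomenology
(hypometria, impaired adduction, vertical-axis differences) but does not
simulate, so magnitudes were fixed once at values a clinician would call
moderate-to-severe, and are not fitted to any result.

`simulate_cohort()` defaults to 50 healthy / 12 MS-like / 9 PD-like
subjects with ages drawn uniformly from 30-79, 40-76 and 59-77 years —
the cohort shape of the original clinical validation — with multiplicative
lognormal jitter (SD 0.1 on the log scale) on each subject's positive
parameters.

What the simulator does *not* emulate: blinks and tracker dropout (the
gaze I/O layer handles them, but simulated traces are complete), main
sequence variability within subject, saccadic curvature, glissadic
overshoot, nystagmus, fatigue drift, and any pupil or torsional signal.
Passing tests therefore demonstrate that the analysis chain recovers known
ground truth under its own generative assumptions — not that it is robust
to every artefact of real recordings.

## Problem sizes and numerical tolerances

The shipped tests run the full chain at the scales the method targets:
20-s trials at 60 Hz (1200 frames), 12-trial protocols, 80-feature
vectors, and 71-subject cohorts (20 seeded replicates for the screening
property). Latency recovery is asserted to one frame (16.7 ms) on
noiseless pursuit and two frames at default noise; detector recall and
precision to 0.9 for saccades >= 2 degrees; Welch type-I error to
0.05 +/- 0.01 over 2000 null replicates; blob FWHM to 1% (discretisation
of the measurement grid); main-sequence parameter recovery to 1% on
noiseless data.

## Known limitations

- At 60 Hz, saccade durations span only 2-4 samples; amplitudes are
  robust, but peak velocities are systematically underestimated for small
  saccades and the detector cannot resolve saccades closer than the
  refractory structure of the threshold window.
- The trailing-window threshold is blind for ~1 s after large saccades
  (see above).
- Directional frequency shares at desk-scale saccade counts (~50-60 task
  saccades per eye per protocol) carry binomial noise of the same order as
  moderate unilateral deficits: halving one eye's nasal saccade rate
  shifts the nasal-bin share by only ~1.3 robust SDs of the healthy
  reference, so per-bin |z| >= 2 flags at that effect size are sporadic.
  The rate reduction itself, and the inter-eye asymmetry, are the reliable
  signatures; the tests assert those.
- F5-F10 are package-defined stand-ins (above); normative comparisons
  across implementations are only meaningful for F1-F4.
- The t-SNE + k-means screen is descriptive, not diagnostic: cluster
  membership depends on the cohort composition, the perplexity and the
  seed, and no claim of patient-level classification is made.
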