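---
title: "Methods: vigilance-state classification and state-dependent physiology"
author: "somnostat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vigilance-state classification and state-dependent physiology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(somnostat)
```

somnostat implements an analysis stack for rodent sleep/anesthesia
neurophysiology: scoring vigilance states (Wake, NREM, REM) from
EEG/EMG/accelerometer recordings, quantifying how neuronal calcium
activity and behavior depend on those states, characterizing
subthreshold membrane resonance from patch-clamp chirp stimuli, and the
exact statistics used to summarize such experiments. Because raw animal
recordings are rarely shareable, the package is organized around a
synthetic-data generator with known ground truth, so every stage can be
validated end to end without any external download. This vignette
documents the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic validation does and does not
demonstrate.

## The synthetic recording model

`simulateSession()` generates a complete multimodal session:

* **Hypnogram.** `simulateStateSequence()` draws a bout-level,
  first-order Markov chain over {WAKE, NREM, REM}. Bout dwell times are
  geometric (memoryless) with configurable per-state means; this is the
  simplest dwell model consistent with treating state transitions as a
  first-order Markov process, which is also how the analysis side
  models them. The default transition matrix has a structurally zero
  diagonal (a bout ends only when the state changes) and no direct
  WAKE to REM transitions, matching normal murine sleep architecture.
  The default mean dwell is 60 windows of 2.5 s (150 s), a realistic
  mouse bout scale that also stands in a sensible ratio to the
  37.5 s persistence minimum used in scoring.
* **Signals.** `synthesizeSignals()` builds EEG as 1/f-shaped
  background noise plus band-limited Gaussian noise (delta 0.5–4 Hz,
  theta 5–9 Hz, and a broadband floor) whose per-sample power follows
  the state sequence; EMG and accelerometer channels are white noise at
  per-state tones. The default contrast is NREM delta power 10 times
  wake, REM theta 5 times wake, and wake EMG/movement tone 5 times
  sleep (atonia in both sleep states). EMG is generated as a
  differential pair around a shared common-mode artifact (slow drift
  plus 50 Hz line) so differential referencing is meaningful. Band
  noise is produced by FFT masking with calibrated one-sided power
  spectral density, so multitaper estimates of the synthesized signal
  can be checked against the profiled values analytically. No
  quantitative per-state spectra are published for this preparation;
  these defaults are calibration choices of the generator, fixed once,
  and all claims about classifier accuracy are conditional on them.
* **Calcium traces.** `synthesizeCalcium()` draws Poisson events per
  state window at per-state rates (defaults are the published median
  per-state transient rates: 0.0677, 0.5076 and 0.2437 events/min in
  Wake, NREM and REM), convolves them with an instantaneous-rise,
  exponentially decaying kernel (tau 1.5 s, a GCaMP-scale decay), and
  adds polynomial drift and white noise (default SD 0.1 dF/F). Event
  amplitudes are uniform on [1.5, 3.0] dF/F — comfortably above the
  detection criteria, deliberately, so that ground truth is recoverable
  and detector failures are attributable to the detector.
* **Membranes.** `simulateMembrane()` integrates the two-variable
  linear membrane C dv/dt = −gL·v − w + i(t), tau_w dw/dt = g1·v − w,
  the minimal linear model of h-current (HCN) subthreshold resonance.
  Integration uses the exact matrix-exponential update for
  piecewise-constant input, so accuracy is set by the stimulus
  discretization, not the integrator. `analyticImpedance()` provides
  the closed form |Z(f)| = |gL + i2&pi;fC + g1/(1 + i2&pi;f·tau_w)|⁻¹
  as an independent oracle. Hodgkin–Huxley-level biophysics is out of
  scope by design.

All generators draw from an explicitly seeded RNG (the global RNG state
is saved and restored around every call) and are bit-reproducible.

## Signal conditioning and spectral estimation

EEG preprocessing decimates 1 kHz recordings to 125 Hz (zero-phase
anti-aliasing low-pass at 80% of the target Nyquist before
subsampling), high-passes at 0.5 Hz with a 4th-order Butterworth
applied forward-backward, and subtracts the per-sample channel mean.
EMG is differentially referenced and high-passed at 300 Hz the same
way. All filtering is zero-phase; the filters remove the signal mean
before filtering (restoring it for low-passes), which is exact for the
DC component and suppresses start-up transients when filtering signals
with large offsets.

Spectrograms are multitaper estimates: 5 s windows, 2.5 s steps, 35
Slepian tapers by default. Thirty-five tapers in a 5 s window implies a
time-bandwidth product NW = 18 (K = 2NW − 1), i.e. about ±3.6 Hz of
spectral smoothing — unusually broad, but it is the setting the staging
pipeline is defined with; both K and NW are configurable, and tests
that need spectral localization (e.g. locating a pure line) use a
narrower family. Slepian sequences are computed from the classical
symmetric tridiagonal commuting matrix (no R package in scope provides
them); they are orthonormal to machine precision. Windows are anchored
so that window k covers [(k−1)·step, (k−1)·step + window]; partial
trailing windows are dropped, and EMG/accelerometer RMS is computed on
the identical grid so the 8-dimensional feature vector is aligned by
construction. Spectrograms are computed on the decimated 125 Hz signal.

Slow-wave activity is the per-window fraction of power in 0.5–4 Hz
relative to a total band. The total band is not prescribed anywhere, so
the package uses 0.5–62.5 Hz: from the high-pass cutoff to the Nyquist
of the decimated record, i.e. all retained power.

## Vigilance-state classification

The staging front end reduces each spectrogram window to six
non-negative matrix factorization (NMF) loadings and appends EMG RMS
and accelerometer RMS (eight features). NMF is fit by multiplicative
updates from a seeded random start; the projection of new windows onto
the fixed basis is a non-negative least squares per window. The
"fraction of spectral variance captured" is defined here as
1 − ‖X − WH‖² / ‖X − X̄‖², with X̄ the mean spectrum replicated across
windows (no standard definition exists; this one reduces to ordinary
explained variance for a mean-centered factorization). On default
synthetic cohorts the rank-6 fit captures well over 90% of spectral
variance.

The classifier is a single-hidden-layer fully connected network
(32 units, softmax output) trained on standardized features with L2
weight decay (1e-3) and a capped iteration count, with a fixed seed.
Weight decay plus the iteration cap plays the role of early stopping as
overfitting control; the network is deliberately the smallest adequate
for 8-dimensional, well-separated features. Training sets are class
balanced by seeded downsampling to the rarest state. Standardization
parameters (per-feature mean/SD) are estimated on training data only
and applied unchanged to held-out data.

Validation is leave-one-subject-out: for each fold the NMF basis, the
standardization, and the classifier are fit on the remaining subjects
only, so no information from the held-out subject can leak into any
trained artifact (a property the test suite checks by comparing trained
artifacts against a run from which the held-out subject is absent
entirely).

Predicted hypnograms pass a persistence filter: scanning left to right,
any maximal run shorter than 15 windows (37.5 s on the 2.5 s grid) is
merged into the preceding surviving state, leading short runs into the
first surviving state. Merging into the *preceding* state is a choice —
only the minimum-duration requirement itself is prescribed — made so a
premature fragment extends the state it interrupts. The filter is
idempotent and never invents labels. If no run reaches the minimum the
input is returned unchanged. Labels for scoring are aligned to the
window grid by the state in effect at each window's opening step; at
bout boundaries a window straddles two states, which injects an
irreducible label ambiguity of roughly one window per bout (about 2% of
windows at the default bout scale). Reported accuracies are therefore
slight underestimates of the classifier's asymptotic separability.

On the default six-subject, two-hour cohort the pipeline reaches about
98% held-out window accuracy after persistence filtering (about 99%
unfiltered). Passing this on synthetic data shows the pipeline is correctly
assembled and leak-free under the stated spectral contrast; it does not
certify performance on real recordings, where spectra are
non-stationary, artifacts abound, and manual labels are themselves
noisy.

## State-dependent calcium quantification

Raw fluorescence traces are detrended with a least-squares cubic
polynomial and divided by the raw-trace mean, so 1.0 means 100% dF/F
relative to mean fluorescence (the conventional reading of a
mean-normalized dF/F). Transients are local maxima that
simultaneously exceed 1.0 dF/F in height and 0.8 dF/F in topographic
prominence and are at least 1 s apart; when two candidates violate the
separation rule the higher peak wins. Prominence is computed
MATLAB-style (extend from the peak until higher terrain or the signal
end; prominence is the height above the higher of the two interval
minima). The two-photon variant instead thresholds an F0-normalized
trace at mean + 3 SD, with F0 the mean of the longest quiescent stretch
of at least 2 s below the trace median ("inactive period" is only
loosely specified; the longest below-median stretch is this package's
operationalization).

Per-state rates are event counts divided by state exposure in minutes.
The state-preference index for state i is S_i = F_i / &Sigma;_j F_j over
the states in which the cell was recorded; S sums to one per included
cell and is invariant to rescaling all rates. The preferred state is
the state with the most transients by count (not rate); ties break
toward greater exposure, then the fixed order Wake < NREM < REM. Cells
with no transients anywhere are excluded. Survivor curves P(s) report
the fraction of cells with S &ge; s; P(0.5) is the fraction of cells more
active in the state of interest than in all others combined. Simplex
summaries embed (S_WAKE, S_NREM, S_REM) barycentrically in an
equilateral triangle.

## Sleep-dynamics metrics

Bout tables are run-length encodings of (ideally persistence-filtered)
hypnograms. Transition matrices count ordered pairs of consecutive
bout states, row-normalized by outgoing counts; the diagonal is
structurally zero, and rows with no outgoing transitions are flagged
undefined rather than silently zeroed. Whether the WAKE to REM cell is
structurally zero or merely unobserved cannot be settled from bout
counts alone, so the matrix reports whatever the data contain and the
generator's default simply never produces such transitions.
Intervention effects are expressed as elementwise probability ratios
against a time-matched baseline, with undefined baseline cells flagged.
Jackknife confidence intervals across subjects use leave-one-out
pseudovalues with a t critical value; for the sample mean this is
exactly the classical t-interval (tested as an identity). Righting
probability uses sliding windows of 10 trials (step 1) with exact
Clopper–Pearson bounds. Body-temperature traces take the median of the
hottest 1% of pixels per thermal frame, smooth with a 5-min moving
median, and contrast a 50-min window centered 90 min post-injection
against the same window 24 h later.

## Membrane resonance and intrinsic properties

Chirp stimuli sweep 0.2–40 Hz logarithmically over 20 s; the phase is
&phi;(t) = 2&pi;f0·T/ln(f1/f0)·(e^{t·ln(f1/f0)/T} − 1). The default
protocol appends 1 s of zero current: recording through the response
decay makes the FFT ratio |Z| = |FFT(V)/FFT(I)| essentially exact for a
linear membrane (two orders of magnitude better near broad impedance
peaks than truncating at the sweep end). The impedance profile is the
raw spectral ratio on the stimulated band — no smoothing by default,
with optional 3-point median smoothing behind a flag, and the resonance
maximum is taken on the raw profile unless that flag is set. Resonant
frequency fR is the argmax; resonance strength is |Z|max over the
(linearly interpolated) impedance at 0.5 Hz; the 3 dB cutoff is the
first frequency above fR where |Z| falls to sqrt(0.5)·|Z|max, flagged
at the band edge when no crossing exists. All three are invariant to
positive rescaling. Cells with fR strictly above 2 Hz are classified
ET-like (extratelencephalic layer-5 physiology).

Step protocols (1 s squares, −150 to +50 pA in 20 pA increments by
default): maximum input resistance is the slope of peak deflection
versus current, steady-state resistance the slope of the mean
deflection over the final 200 ms of the step (the steady-state window
length is this package's choice), both fit over hyperpolarizing steps
only (&le; −10 pA) to stay on the linear part of the I–V relation. Sag is
their ratio. Rebound amplitude is the signed post-offset overshoot
relative to pre-step baseline (an ohmic cell relaxes without overshoot,
giving a zero rebound slope), regressed on steady-state potential.
Sweeps containing spikes are excluded. Suprathreshold metrics follow
the stated rules: rheobase is the minimal current with at least one
spike; the AP threshold is the voltage at the first point where dV/dt
exceeds 20 V/s (found by walking back from the peak); half-width is
measured at half the amplitude between that threshold and the peak with
linear interpolation of the crossings; the first ISI comes from the
minimal current driving at least two spikes; spike-frequency
accommodation is the second ISI over the last ISI in the first train of
at least ten spikes. Metrics whose defining sweep does not exist are NA
with the reason visible in the per-sweep spike counts.

## Statistics

Pearson chi-square is computed without continuity correction (the only
convention that reproduces published 2x2 statistics of this kind);
expected counts of zero are an error. The two-sided Fisher exact
p-value follows the point-probability convention (sum of
hypergeometric probabilities not exceeding the observed table's), and
the test suite verifies agreement with exhaustive enumeration for every
2x2 table with total at most 30. Binomial pmf/tail are exact;
Clopper–Pearson intervals come from the beta-quantile identities.
Positivity calling for stain intensities fits a 2-component Gaussian
mixture by EM with deterministic initialization (means at the 25th/75th
percentiles, tolerance 1e-8, at most 500 iterations) and requires a
posterior above 0.9 for the higher-mean component; near-constant input
is flagged degenerate and everything is called negative. Soma
candidates are filtered on inclusive bounds (area 30–1500 px,
circularity 0.3–1.7, equivalent diameter 5–40 px; 3-D volume strictly
below 2000 µm³). Colocalization flags an ROI when at least 25% (by
default; the fraction is a free parameter, unspecified upstream) of its
pixels overlap some ROI of the reference set.

## Problem sizes and scope of the validation

The package's own validation runs at desk scale: six synthetic subjects
of two hours for the staging benchmark, 500-bout sequences across ten
seeds for transition-matrix recovery, 60 minutes of exposure per state
across ten seeds for rate recovery, and 20 s chirps at 0.1 ms
resolution for the impedance oracle. Quantities that depend on a
specific animal cohort (absolute c-Fos densities, accuracies against
manual scores on real mice, post-drug sleep-time changes, absolute
temperature drops) are outside what synthetic data can certify; the
corresponding code paths are instead validated by construction against
generator ground truth, closed forms, or independent oracles
(enumeration for Fisher, the analytic impedance for ZAP, mclust for the
mixture model).

Other known limitations: no artifact rejection or line-noise notch in
the EEG path (not part of the modeled pipeline); detection operates on
traces, not videos (ROI extraction, motion correction and spike
inference are upstream and out of scope); the EDF reader handles
continuous uniform-rate recordings only; and the session container is a
documented plain-text directory layout rather than a binary
hierarchical format, keeping every artifact inspectable and
version-controllable.
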