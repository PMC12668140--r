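# somnostat

Analysis toolkit for rodent sleep and anesthesia neurophysiology. It
addresses a common experimental design in systems neuroscience: mice
carry EEG/EMG/accelerometer implants (1 kHz) while neuronal activity is
recorded as calcium fluorescence or, ex vivo, with patch-clamp
protocols, and the scientific questions are *state-conditioned* — which
neurons fire preferentially in NREM sleep or under anesthesia, how an
intervention reshapes sleep-state dynamics, and whether a cell class
shows a distinctive membrane resonance. The package is written for
researchers who need those analyses reproducible and testable without
access to the original animals' recordings: a synthetic-data generator
with known ground truth stands in for the animal, and every analysis
stage is validated against it.

## What it computes

**Vigilance-state classification.** EEG is decimated to 125 Hz,
high-passed (4th-order Butterworth, 0.5 Hz, zero-phase) and mean
re-referenced; EMG is differentially referenced and high-passed at
300 Hz. Multitaper spectrograms (35 Slepian tapers, 5 s window, 2.5 s
step) are reduced by rank-6 non-negative matrix factorization, and the
six loadings plus EMG RMS and accelerometer RMS form an 8-dimensional
feature vector per window. A single-hidden-layer feedforward network
(softmax over Wake/NREM/REM) is trained on class-balanced, standardized
features and validated leave-one-subject-out; classified states must
persist for at least 15 consecutive windows (37.5 s).

**Sleep dynamics.** Transitions between Wake, NREM and REM are modeled
as a bout-level Markov process: `transitionMatrix()` estimates the
3&times;3 row-stochastic matrix (zero diagonal), `transitionRatio()`
normalizes an intervention period by a zeitgeber-time-matched baseline,
and `boutTable()`/`timeInState()`/`bandFraction()` provide bout
durations, time-in-state fractions and slow-wave activity (the fraction
of EEG power in 0.5–4 Hz). Jackknife CIs across subjects, sliding-window
righting-reflex probabilities with exact binomial bounds, and
thermal-imaging temperature deltas round out the behavioral metrics.

**State-dependent calcium activity.** Traces are detrended (cubic) and
mean-normalized to &Delta;F/F; transients are peaks exceeding 100%
&Delta;F/F with at least 80% prominence and 1 s separation (a 3-SD
threshold variant covers two-photon data). Per-state rates F_i
(transients/min) give the state-preference index

&nbsp;&nbsp;&nbsp;&nbsp;S_i = F_i / &Sigma;_j F_j,

with survivor curves P(s) = fraction of cells with S &ge; s and simplex
summaries of 3-state preferences.

**Membrane resonance (ZAP).** Chirp currents sweep 0.2–40 Hz
logarithmically over 20 s; the impedance profile is
|Z(f)| = |FFT(V)/FFT(I)| in M&Omega;. Resonant frequency fR (argmax),
resonance strength (|Z|max / |Z|(0.5 Hz)) and the 3 dB cutoff are
extracted, and fR &gt; 2 Hz marks ET-like (extratelencephalic L5)
physiology. Input resistance, sag, rebound slope and spike metrics come
from square-step protocols. A linear two-variable membrane model with
closed-form impedance serves as the built-in oracle.

**Exact statistics.** Pearson chi-square (no continuity correction),
two-sided Fisher exact with Bonferroni, exact binomial pmf/tail and
Clopper–Pearson intervals, fold changes of median rates, 2-component
Gaussian-mixture positivity calling for stain intensities, soma
candidate filtering and ROI colocalization.

## Worked example

```r
library(somnostat)

sess <- simulateSession(durationS = 1800, nCells = 4, seed = 7)
sess
#> SyntheticSession 's1' (seed 7)
#>   EEG 2 ch, EMG 2 ch, accel 3 ch @ 1000 Hz, 1800.0 s
#>   4 calcium cells @ 4 Hz; 720 state windows of 2.5 s

cal <- detectTransients(sess@calcium[, 1], fs = sess@calciumFs)
sr  <- stateRates(cal, sess@states)
sr
#>      state events exposureMin      rate
#> WAKE  WAKE      0   11.000000 0.0000000
#> NREM  NREM      7   13.791667 0.5075529
#> REM    REM      2    5.208333 0.3840000

sp <- statePreference(sr)
round(sp$S, 3)
#>  WAKE  NREM   REM
#> 0.000 0.569 0.431
sp$preferred
#> [1] "NREM"

transitionMatrix(generatingBouts(sess@states)$state)$probabilities
#>       to
#> from   WAKE NREM REM
#>   WAKE 0.00 1.00 0.0
#>   NREM 0.50 0.00 0.5
#>   REM  0.33 0.67 0.0
```

The cell fires at 0.51 transients/min in NREM and not at all in
wakefulness (the generator's default rates are the study-scale
medians), so its preference index concentrates on NREM and the cell is
called NREM-preferring. The bout-level transition matrix estimated from
the 30-minute hypnogram already resembles the generator's sleep
architecture (wake bouts always end in NREM; no direct WAKE to REM
transitions).

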