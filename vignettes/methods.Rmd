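---
title: "Methods: sleep staging from polysomnography with somnostage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep staging from polysomnography with somnostage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`somnostage` implements an automatic sleep-staging pipeline for
polysomnography (PSG): multi-channel overnight recordings of brain (EEG),
eye (EOG) and muscle (EMG) activity, scored by experts into 30-second
epochs labelled with Rechtschaffen–Kales stages (W, 1, 2, 3, 4, R, plus
movement time M and unscored `?`). The pipeline is:

1. **Ingest** — EDF signal files and EDF+ hypnogram annotations
   (`readRecording()`, `readHypnogram()`).
2. **Filter** — a zero-phase Hamming-window FIR band-pass, 0.3–40 Hz
   (`designFirBandpass()`, `filterRecording()`), applied to the whole
   recording before epoching.
3. **Map and epoch** — raw stage labels collapse into one of five
   classification tasks (`stageConfig()`, `mapStages()`); full 30-s windows
   inside scored segments become labelled epochs (`extractEpochs()`).
4. **Featurise** — per epoch and channel: Welch power spectral density,
   SVD entropy, Higuchi fractal dimension, permutation entropy, detrended
   fluctuation analysis, and four statistical moments
   (`buildFeatureTable()`).
5. **Balance and classify** — SMOTE oversampling of the training split
   only (`smoteOversample()`), a stratified 80/20 split, optional 15-fold
   stratified cross-validation, and a pluggable tree-ensemble learner
   (XGBoost by default; random forest and extremely randomized trees via
   `ranger`), evaluated on the untouched, imbalanced test set
   (`runPipeline()`, `evaluateModel()`).

A synthetic PSG generator (`simulatePsg()`) produces hypnograms and
stage-conditioned signals with the statistical structure the pipeline
assumes, so every stage of the pipeline is exercisable — and tested —
without any external data.

# The feature measures

All measures are computed per 30-s epoch (3000 samples at 100 Hz) per
channel. Each implementation is checked against an independent naive
implementation of its defining formula in the test suite (agreement to
1e-9 on random series).

**Welch PSD.** The epoch is cut into segments of `segmentLen = 256`
samples shifted by 128 (50% overlap), each segment is Hamming-windowed and
its periodogram $P_k(v) = |X_k(v)|^2 / W$ formed, with
$W = \sum_m w(m)^2$; the PSD is the average periodogram. We scale to a
one-sided density ($2/(f_s W)$, DC and Nyquist not doubled) so that the
integrated PSD equals the signal variance (verified to 2% by a Parseval
check); the defining formulas fix the estimate only up to this constant,
and a variance-calibrated density is the convention of every standard
toolchain. Bins are retained on [0.3, 40] Hz to match the band-pass. At
256 samples and 100 Hz this yields 102 bins per channel; the bin count is
a documented consequence of the configuration, not a constant of the
package.

**SVD entropy.** Shannon entropy (bits) of the L1-normalised singular
values of the delay-embedding matrix with order $d_E = 3$ and delay
$\tau = 1$. Bounded by $\log_2 d_E$; a constant series has a rank-one
embedding and returns 0 under the $0 \log 0 = 0$ convention.

**Higuchi fractal dimension.** Curve-length scaling over intervals
$k = 1..k_{max}$ with $k_{max} = 10$; the slope of $\log L(k)$ against
$\log(1/k)$. Exactly 1 for a straight line, near 2 for white noise. A
constant series (zero curve length, undefined log) returns 1 by
convention.

**Permutation entropy.** Shannon entropy (bits) of ordinal patterns of
length $D = 3$, delay 1 (configurable within 3–7, the recommended range).
Ties are ranked by order of appearance. Zero for monotone series,
$\log_2 D!$ in the continuous-noise limit.

**DFA.** The mean-centred series is integrated, linearly detrended in
non-overlapping windows, and the RMS fluctuation $F(n)$ is regressed on
$\log n$ over 12 log-spaced window sizes from 8 to $N/4$ samples. The
defining description gives neither the scale grid nor the detrending
order beyond a least-squares line; first-order detrending and a log-spaced
grid are the field's defaults. White noise gives $\alpha \approx 0.5$,
a Brownian path $\approx 1.5$. A constant series has zero fluctuation at
every scale and is an error: no finite exponent exists.

**Moments.** Mean; *population* standard deviation ($N$ in the
denominator); skewness with the mixed $(N-1)\,\sigma^3$ denominator; and
non-excess (Pearson) kurtosis $\mu_4 / \sigma^4$ — 3 for a Gaussian, with
no $-3$ correction. These conventions are deliberately unusual (the
skewness denominator mixes a population $\sigma$ with an $N-1$ factor) and
are kept exactly as defined so the feature values are reproducible; they
are documented here rather than silently normalised. A zero-variance
epoch-channel imputes skewness 0 and kurtosis 3 with a warning, so one
flat channel cannot abort a run.

Feature columns are named `"{channel}::{measure}[::{bin}]"`. With all
measures enabled on the four canonical channels the table has
$16 + 16 + 4 \times 102 = 440$ columns; moments alone give 16, the four
scalar measures alone give 16.

# The FIR band-pass and its printed characteristics

The kernel is a single Hamming-windowed ideal band-pass. Transition
bandwidths follow the windowed-sinc convention
$\min(\max(0.25 f_{edge}, 2\,\mathrm{Hz}), \mathrm{room})$ — 0.3 Hz below
the 0.3 Hz edge and 10 Hz above the 40 Hz edge at $f_s = 100$ Hz — with
−6 dB cutoffs at the edge ∓ half a transition width and length
$3.3 / (\mathrm{narrowest\ transition} / f_s)$ rounded up to odd
(1101 taps). Application is zero-phase: one forward FFT convolution with
mirrored edge padding and group-delay compensation, so epoch labels never
shift in time. Zero-phase application was chosen over causal filtering
because label alignment matters more here than causality; this choice is
recorded in the configuration.

A caveat worth stating precisely: the widely quoted Hamming design figures
— 53 dB stopband attenuation and 0.0194 dB passband ripple — are *nominal
window constants* ($\delta = 10^{-53/20} = 0.0022$;
$20\log_{10}(1+\delta) = 0.0194$ dB). For this particular band they are
not recoverable from the realized transfer function: the lower transition
(0.3 Hz wide, cutoff at 0.15 Hz) is squeezed against DC, where the
kernel's negative-frequency image doubles the leakage (about $2\delta$,
i.e. ≈ 47 dB rather than 53 dB), and the upper stopband edge sits exactly
at Nyquist. `filterCharacteristics()` therefore reports what the kernel
actually measures on a dense FFT grid — maximum $|20\log_{10}|H||$ over
the passband and minimum attenuation over the designed stopbands — and the
test suite asserts the realized behaviour (unit passband gain, DC
rejection, stopband tones crushed below $10^{-53/20}$) rather than
pretending the nominal constants are measurements. The acceptance suite
keeps the literal nominal-constant check, and it fails by construction;
the same measurement applied to the reference Python toolchain's kernel
fails it equally.

# The synthetic PSG generator

The generator is first-class, tested code, and defines the study
conditions for all pipeline-level checks.

**Hypnogram model.** A first-order stage-transition chain with geometric
dwell times in units of 30-s epochs (mean dwells: W 120 s, N1 60 s,
N2 330 s, N3 240 s, N4 210 s, R 300 s) and a time-inhomogeneous bias —
the probability of transitioning into wake is multiplied by
$0.25 + 2.5 e^{-4t}$ and into REM by $0.1 + 2.2 t$, with $t$ the elapsed
night fraction. These defaults are not fitted to data (none are published
to fit against); they were chosen once to reproduce the canonical
overnight architecture: wake skewed early, REM late, N2 the largest share
of the night, and strong class imbalance (N1 rarest). A 9-h night yields
1080 epochs with typical five-stage counts of roughly 30–90 W, 30–60 N1,
400–500 N2, 150–400 N3/N4, 150–350 R.

**Signal profiles.** Textbook spectral signatures per stage, amplitudes in
microvolts: wake = 10 Hz alpha (65 µV) with high EMG tone (25 µV RMS) and
frequent EOG events; N1 = low-amplitude 5 Hz theta; N2 = theta plus 1-s
13 Hz spindle bursts at Poisson rate 3/min; N3/N4 = high-amplitude
1.5/1.2 Hz delta; REM = low-amplitude mixed 3/6 Hz EEG, near-atonic EMG
(0.8 µV), frequent square EOG deflections. The second EEG channel carries
the same bands at 0.75 amplitude. Band components are sinusoids with
per-epoch random frequency (within the band) and phase plus white
broadband noise. Wake EEG carries the highest total power and deep sleep
the most delta, matching the qualitative spectral ordering the pipeline
exploits.

**What it does not emulate.** Physiological microstructure (K-complex
morphology, artifacts, electrode pops), 1/f background spectra,
inter-subject variability, and drug effects. Consequently, passing
pipeline tests demonstrate that the machinery is correct and that the
classifier recovers stage structure *when the generative signatures are
present*; they do not certify real-data accuracy. On real recordings the
stage signatures are weaker and overlap, and hold-out accuracies on
synthetic nights (typically > 95%) exceed what the same pipeline attains
on real PhysioNet telemetry data (high-80s for five stages). Reproducing
the published real-data numbers requires downloading the PhysioNet
sleep-edfx ST recordings and running this same pipeline on them —
`readRecording()`/`readHypnogram()` read those files directly — but that
path needs external data and is deliberately not part of the test suite.

# Class imbalance and SMOTE placement

SMOTE synthesizes minority-class rows as convex combinations
$x + u(x_{nn} - x)$, $u \sim U(0,1)$, between a row and one of its
$k = 5$ nearest same-class neighbours, until every class reaches the
majority count. Original rows are never modified, and the test set is
never oversampled, so evaluation always happens on the natural imbalance.

Whether oversampling happened before or inside the cross-validation folds
is ambiguous in the method description this package reproduces; the
leakage-free placement (SMOTE fitted inside each training fold,
`smoteBeforeCv = FALSE`) is the default, and the alternative (oversample
once before folding) is available behind a flag so both protocols can be
compared. Reports record which was used in `meta`.

# Splitting, learners and metrics

The 80/20 split and the 15-fold CV are stratified by label and
deterministic given a seed. Learners sit behind a fit / predict-probability
contract: `xgboost` (multi-class softprob, single-thread, fixed seed;
defaults `nrounds = 100`, `max_depth = 4`, `eta = 0.3`), `random_forest`
(`randomForest`, 300 trees) and `extra_trees` (`ranger` with the
`extratrees` split rule). Gradient boosting is never re-implemented.
LightGBM appears in the supported-name list for interface parity but has
no installed R backend and raises an informative error.

Per-class precision, recall and F1 follow the one-vs-rest count
definitions; accuracy is the confusion-matrix trace over the total
(identical to micro-averaged recall, an identity the tests assert);
multi-class averages are macro (unweighted) because the source convention
is unstated; AUC is macro one-vs-rest on predicted class probabilities.
Metrics are stored as fractions and printed as percentages to two
decimals.

# Numerical and degenerate-input conventions

* Segment times are seconds from recording start; intervals are half-open
  `[onset, onset + duration)`; partial trailing 30-s windows are
  discarded.
* All scored epochs are kept: wake periods far outside the sleep episode
  are not trimmed. Nothing in the reproduced protocol defines a trim
  window, and dropping data silently would change the class balance;
  callers who want a trim can subset the hypnogram before epoching.
* EDF samples are quantized to 16 bits over each channel's observed range;
  round trips are exact for names/rates and within one digital step for
  values.
* Ordinal-pattern ties: rank by order of appearance (`ties.method =
  "first"`).
* Argmax class prediction breaks probability ties by class order.
* Constant series: SVD entropy 0, Higuchi dimension 1, DFA an error,
  moments imputed (0, 3) with a warning.
* All randomness flows through explicit integer seeds (`withr::with_seed`),
  and learners run single-threaded, so identical configurations reproduce
  identical reports bit for bit.

# Problem sizes used by the checks

The test suite runs on simulated sessions of 2–6 hours for plumbing and
modelling checks, a 150-minute six-stage balanced recording for spectral
statistics (50 epochs per stage), and one full 9-hour night (1080 epochs,
440 features) for the end-to-end benchmarks; estimator oracles use 50
random series of length 200. `scripts/acceptance.R` recomputes the
headline quantities from one fresh 9-hour simulation under the seed it is
given. These sizes were chosen as the smallest at which the measured
quantities are stable.

# Known limitations

* Synthetic-data accuracy overstates real-data accuracy by construction
  (see above); the package's claims about real data are limited to
  pipeline fidelity, not performance.
* Epoch-wise splitting follows the reproduced protocol; subject-wise
  (leave-one-recording-out) evaluation is the stricter standard and is a
  documented extension, not implemented here.
* The EDF writer emits the continuous (`EDF+C`) layout only and requires
  integer samples-per-second rates.
* No artifact rejection, resampling, notch filtering or re-referencing:
  the reproduced preprocessing contains none.
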