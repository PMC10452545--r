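# somnostage

Automatic sleep staging from polysomnography (PSG) in R.

Overnight PSG — two EEG derivations (Fpz-Cz, Pz-Oz), horizontal EOG and
submental EMG, sampled at 100 Hz — is scored by experts into 30-second
epochs labelled with the Rechtschaffen–Kales stages W, 1, 2, 3, 4, R
(plus movement time and unscored). `somnostage` reproduces a
feature-engineering approach to automating that scoring: instead of a
deep network it extracts a diverse set of per-epoch, per-channel signal
descriptors and feeds them to gradient-boosted trees. It is aimed at
sleep researchers and biomedical-signal people who want a transparent,
testable staging pipeline whose every numerical step is inspectable.

## The method

For each 30-s epoch (3000 samples) of each of the four channels:

* **Welch power spectral density** — average periodogram over Hamming
  windowed 256-sample segments with 50% overlap,
  `S_x(v) = (1/K) Σ_k |X_k(v)|² / W`, `W = Σ w²(m)`, one column per
  retained frequency bin on [0.3, 40] Hz;
* **SVD entropy** — `H = −Σ σ̄_i log₂ σ̄_i` over the normalised singular
  values of the delay-embedding matrix (order 3, delay 1);
* **Higuchi fractal dimension** — slope of `log L(k)` vs `log(1/k)`,
  `k = 1..10`, of the sub-sampled curve lengths;
* **permutation entropy** — `−Σ p_i log₂ p_i` over ordinal patterns of
  length 3;
* **detrended fluctuation analysis** — scaling exponent α of the RMS
  fluctuation of the integrated, per-window detrended series;
* **moments** — mean, population SD, skewness, Pearson kurtosis
  (μ₄/σ⁴).

Signals are band-pass filtered (zero-phase Hamming-window FIR,
0.3–40 Hz) before epoching. Raw stage labels are collapsed into one of
five classification tasks — 5-stage (W / N1 / N2 / N3-N4 / R), 4-stage
(W / Light / Deep / R), 3-stage (W / Non-REM / REM), REM-vs-NREM and
Awake-vs-Asleep. Training data are rebalanced with SMOTE (synthetic
minority rows interpolated between same-class nearest neighbours);
the held-out test data never are. Classification uses XGBoost by default
(random forest and extra trees are plug-ins) with a stratified 80/20
split and optional 15-fold stratified cross-validation.

A built-in synthetic PSG generator (`simulatePsg()`) produces overnight
hypnograms (first-order stage chain, wake early / REM late, N2
dominant, N1 rare) and stage-conditioned signals (alpha in wake, theta
plus 13 Hz spindle bursts in N2, high-amplitude delta in deep sleep,
atonic EMG in REM), so the entire pipeline runs and is tested with no
downloads. Minimal EDF/EDF+ readers and writers are included; real
PhysioNet sleep-edfx telemetry files load through the same
`readRecording()` / `readHypnogram()` calls.

## Worked example

```r
library(somnostage)

sim <- simulatePsg(hours = 6, seed = 42)
sim$hypnogram
#> Hypnogram: 86 segment(s), 21600 s total
#>   time per stage (s): 1=870 2=8700 3=3540 4=2820 R=3450 W=2220

report <- runPipeline(list(stages = "five", seed = 42, hours = 6))
report
#> EvaluationReport
#>   hold-out accuracy: 96.53%   macro AUC: 1.0000
#>   per-class metrics (%):
#>     W          precision 100.00  recall  80.00  F1  88.89  n=15
#>     N1         precision  54.55  recall 100.00  F1  70.59  n=6
#>     N2         precision 100.00  recall 100.00  F1 100.00  n=58
#>     N3/N4      precision 100.00  recall 100.00  F1 100.00  n=42
#>     R          precision 100.00  recall  91.30  F1  95.45  n=23
```

The hypnogram summary shows the simulated night: N2 holds the largest
share (8700 s), N1 the smallest (870 s) — the class imbalance that makes
SMOTE necessary. The report is the hold-out evaluation of an XGBoost
model trained on SMOTE-balanced features from that night: the `n` column
is the (imbalanced) test support per stage, and the weak N1 precision at
six test epochs shows exactly the behaviour expected of the rarest
class. Synthetic nights are deliberately easier than real recordings —
the generator plants the textbook stage signatures the features are
designed to detect — so accuracies here sit above what the same pipeline
produces on real telemetry data.

Individual estimators are ordinary functions:

```r
permutationEntropy(c(4, 7, 9, 10, 6, 11, 3), order = 3)  # 1.521928 bits
higuchiFd(rnorm(3000))                                   # ~2 (white noise)
dfa(cumsum(rnorm(10000)))                                # ~1.5 (Brownian)
```

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/somnostage.R simulate --hours 9 --seed 1 --out fixtures/
Rscript inst/cli/somnostage.R run --simulate --stages three --seed 1 --out out/
```

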