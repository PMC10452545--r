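# Shared synthetic fixtures, built once per test run.

# A short overnight-like session for I/O and pipeline plumbing tests.
sharedSession <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulatePsg(hours = 2, seed = 101)
    cache
  }
})

# One long segment per stage (50 epochs each) so per-stage spectral
# statistics have usable standard errors.
stageBalancedHypnogram <- function(epochsPerStage = 50) {
  stages <- c("W", "1", "2", "3", "4", "R")
  dur <- rep(epochsPerStage * 30, length(stages))
  hypnogram(onset = cumsum(c(0, dur[-length(dur)])), duration = dur,
            label = stages)
}

stageBalancedRecording <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generateRecording(stageBalancedHypnogram(), seed = 202)
    cache
  }
})

# Mean one-sided band power of an epoch series via the package Welch PSD.
bandPower <- function(x, fs, lo, hi) {
  p <- welchPsd(x, fs, fmin = 0.05, fmax = fs / 2)
  sel <- p$freq >= lo & p$freq < hi
  sum(p$psd[sel]) * (p$freq[2] - p$freq[1])
}

# Small labelled feature table with separable classes for modeling tests.
toyFeatureTable <- function(n = 60, classes = c("A", "B"), sdNoise = 0.3,
                            seed = 1, separation = 3) {
  withr::with_seed(seed, {
    k <- length(classes)
    y <- rep(classes, length.out = n)
    X <- cbind(f1 = separation * match(y, classes) + rnorm(n, 0, sdNoise),
               f2 = rnorm(n),
               f3 = separation * (match(y, classes) %% 2) +
                 rnorm(n, 0, sdNoise),
               f4 = rnorm(n))
    sleepFeatureTable(X, labels = y)
  })
}
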