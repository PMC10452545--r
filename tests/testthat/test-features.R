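# Feature estimators: brute-force oracle equivalence, closed forms and
# limits, invariants, and feature-table assembly.

test_that("every estimator matches its naive brute-force oracle to 1e-9", {
  set.seed(42)
  scales <- c(8, 12, 16, 24, 32, 50)
  for (i in 1:50) {
    x <- rnorm(200) + 0.5 * sin(2 * pi * runif(1, 1, 20) * (1:200) / 100)
    w1 <- welchPsd(x, fs = 100, segmentLen = 64L, shift = 32L,
                   fmin = 0.3, fmax = 40)
    w2 <- oracleWelch(x, fs = 100, M = 64, S = 32, fmin = 0.3, fmax = 40)
    expect_equal(w1$freq, w2$freq, tolerance = 1e-12)
    expect_equal(w1$psd, w2$psd, tolerance = 1e-9)
    expect_equal(svdEntropy(x, 3, 1), oracleSvdEntropy(x, 3, 1),
                 tolerance = 1e-9)
    expect_equal(higuchiFd(x, 10), oracleHiguchi(x, 10), tolerance = 1e-9)
    expect_equal(permutationEntropy(x, 3, 1), oraclePermEntropy(x, 3, 1),
                 tolerance = 1e-9)
    expect_equal(dfa(x, scales), oracleDfa(x, scales), tolerance = 1e-9)
    expect_equal(signalMoments(x), oracleMoments(x), tolerance = 1e-9)
  }
})

test_that("permutation entropy reproduces the worked 7-point example and its limits", {
  # ordinal patterns of (4,7,9,10,6,11,3) at D=3: {012:2, 201:2, 102:1}
  x <- c(4, 7, 9, 10, 6, 11, 3)
  expect_equal(oraclePermEntropy(x, 3, 1),
               -(0.4 * log2(0.4) * 2 + 0.2 * log2(0.2)))
  expect_equal(permutationEntropy(x, 3, 1), 1.5219, tolerance = 1e-4)
  expect_equal(permutationEntropy(1:500, 3, 1), 0)
  set.seed(3)
  expect_equal(permutationEntropy(runif(1e4), 3, 1), log2(6),
               tolerance = 0.05)
})

test_that("Higuchi dimension hits its closed-form anchors and range", {
  expect_equal(higuchiFd(as.numeric(1:3000), 10), 1, tolerance = 0.01)
  set.seed(5)
  expect_equal(higuchiFd(rnorm(3000), 10), 2, tolerance = 0.1)
  for (s in 1:10) {
    set.seed(s)
    x <- cumsum(rnorm(500)) + sin((1:500) / 10)
    d <- higuchiFd(x, 10)
    expect_gte(d, 1 - 0.05); expect_lte(d, 2 + 0.05)
  }
})

test_that("adding noise to a sinusoid never decreases the Higuchi dimension", {
  t <- (1:1000) / 100
  base <- sin(2 * pi * 5 * t)
  for (s in 1:20) {
    set.seed(s)
    noise <- rnorm(1000)
    d <- vapply(c(0, 0.05, 0.2, 0.5, 1, 2), function(a)
      higuchiFd(base + a * noise, 10), numeric(1))
    expect_true(all(diff(d) > -1e-8))
  }
})

test_that("DFA recovers the white-noise and Brownian scaling exponents", {
  aW <- aB <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    z <- rnorm(1e4)
    aW[s] <- dfa(z)
    aB[s] <- dfa(cumsum(z))
  }
  expect_equal(mean(aW), 0.5, tolerance = 0.05)
  expect_equal(mean(aB), 1.5, tolerance = 0.1)
  set.seed(1); x <- rnorm(2000)
  expect_equal(dfa(x), dfa(5 * x), tolerance = 1e-12)  # scale invariance
  expect_error(dfa(rep(1, 1000)), "constant")
})

test_that("SVD entropy spans constant to isotropic-noise limits", {
  expect_equal(svdEntropy(rep(2, 100)), 0, tolerance = 1e-9)
  set.seed(6)
  expect_equal(svdEntropy(rnorm(3000), 3, 1), log2(3), tolerance = 0.05)
  hSin <- svdEntropy(sin(2 * pi * 7 * (1:3000) / 100), 3, 1)
  expect_gt(hSin, 0)
  expect_lt(hSin, log2(3))
})

test_that("entropies stay inside their theoretical bounds", {
  for (s in 1:15) {
    set.seed(s)
    x <- cumsum(rnorm(300)) * runif(1, 0.1, 10)
    D <- sample(3:5, 1)
    pe <- permutationEntropy(x, D, 1)
    expect_gte(pe, 0); expect_lte(pe, log2(factorial(D)))
    h <- svdEntropy(x, D, 1)
    expect_gte(h, -1e-12); expect_lte(h, log2(D))
  }
})

test_that("Welch PSD integrates to the signal variance and localises tones", {
  x <- sin(2 * pi * 10 * (1:3000) / 100)
  p <- welchPsd(x, 100, fmin = 0, fmax = 50)
  df <- p$freq[2] - p$freq[1]
  expect_equal(sum(p$psd) * df, var(x) * (length(x) - 1) / length(x),
               tolerance = 0.02)
  pk <- welchPsd(x, 100)
  expect_equal(pk$freq[which.max(pk$psd)], 10, tolerance = 100 / 256)
  expect_equal(welchPsd(numeric(3000), 100)$psd,
               rep(0, length(pk$freq)))
  expect_error(welchPsd(rnorm(100), 100, segmentLen = 256), "shorter")
})

test_that("averaged white-noise PSD is flat across the retained band", {
  set.seed(9)
  acc <- 0
  for (i in 1:100) acc <- acc + welchPsd(rnorm(3000), 100, fmin = 1,
                                         fmax = 40)$psd
  expect_lt(max(acc) / min(acc), 3)
})

test_that("moments follow the stated conventions", {
  m <- signalMoments(1:5)
  expect_equal(unname(m), c(3, sqrt(2), 0, 1.7))
  sym <- c(-3, -1, 0, 1, 3)
  expect_equal(signalMoments(sym)[["skewness"]], 0)
  set.seed(10)
  expect_equal(signalMoments(rnorm(1e5))[["kurtosis"]], 3, tolerance = 0.2)
  expect_warning(mz <- signalMoments(rep(7, 50)), "zero-variance")
  expect_equal(unname(mz), c(7, 0, 0, 3))
})

test_that("feature tables have the documented column structure", {
  sim <- sharedSession()
  eps <- extractEpochs(filterRecording(sim$recording),
                       mapStages(sim$hypnogram, stageConfig("five")))
  ftM <- buildFeatureTable(eps, measures = "moments")
  expect_length(featureNames(ftM), 16)
  ftS <- buildFeatureTable(eps, measures = c("svd_entropy", "higuchi_fd",
                                             "permutation_entropy", "dfa"))
  expect_length(featureNames(ftS), 16)   # 4 channels x 4 scalar measures
  ftAll <- buildFeatureTable(eps, measures = "all")
  nBins <- sum(grepl("^EEG Fpz-Cz::psd::", featureNames(ftAll)))
  expect_length(featureNames(ftAll), 16 + 16 + 4 * nBins)
  expect_equal(nEpochs(ftAll), nEpochs(eps))
  expect_identical(as.character(epochLabels(ftAll)),
                   as.character(epochLabels(eps)))
  expect_true(all(is.finite(featureMatrix(ftAll))))
  expect_error(buildFeatureTable(eps, measures = "wavelet"), "wavelet")
})

test_that("feature values depend on channel names, not storage order", {
  h <- hypnogram(0, 90, "2")
  rec <- generateRecording(h, seed = 30)
  recPerm <- psgRecording(rec@signals[c(3, 1, 4, 2)], fs = rec@fs[c(3, 1, 4, 2)],
                          units = rec@units[c(3, 1, 4, 2)])
  m <- mapStages(h, stageConfig("five"))
  ft1 <- buildFeatureTable(extractEpochs(rec, m), measures = "moments")
  ft2 <- buildFeatureTable(extractEpochs(recPerm, m), measures = "moments")
  expect_identical(featureNames(ft1), featureNames(ft2))
  expect_equal(featureMatrix(ft1), featureMatrix(ft2))
})
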