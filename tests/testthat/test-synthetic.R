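# Synthetic PSG generator: hypnogram structure, stage-conditioned signal
# content, determinism and fixture round trips.

test_that("identical seeds give bit-identical hypnograms and signals", {
  m <- defaultHypnogramModel(hours = 1)
  h1 <- generateHypnogram(m, seed = 7)
  h2 <- generateHypnogram(m, seed = 7)
  expect_identical(segments(h1), segments(h2))
  r1 <- generateRecording(h1, seed = 9)
  r2 <- generateRecording(h2, seed = 9)
  expect_identical(r1@signals, r2@signals)
  h3 <- generateHypnogram(m, seed = 8)
  expect_false(identical(segments(h1), segments(h3)))
})

test_that("an absorbing chain stays in its initial stage", {
  m <- defaultHypnogramModel(hours = 1)
  m$transitionMatrix <- diag(6)
  dimnames(m$transitionMatrix) <- dimnames(defaultHypnogramModel()$transitionMatrix)
  m$wakeBias <- NULL; m$remBias <- NULL
  h <- generateHypnogram(m, seed = 1)
  seg <- segments(h)
  expect_identical(seg$label, "W")
  expect_equal(seg$duration, 3600)
})

test_that("invalid transition matrices are rejected", {
  m <- defaultHypnogramModel()
  m$transitionMatrix[1, 1] <- 5
  expect_error(generateHypnogram(m, seed = 1), "transition")
  m2 <- defaultHypnogramModel()
  m2$meanDwell["W"] <- 10
  expect_error(generateHypnogram(m2, seed = 1), "dwell")
})

test_that("overnight hypnograms give N2 the largest total duration and skew wake early, REM late", {
  h <- generateHypnogram(defaultHypnogramModel(hours = 9), seed = 1)
  seg <- segments(h)
  expect_equal(sum(seg$duration), 9 * 3600)
  expect_true(all(seg$duration %% 30 == 0))
  tot <- tapply(seg$duration, seg$label, sum)
  expect_identical(names(which.max(tot)), "2")
  # centre of mass of wake time in the first half, REM's in the second
  mid <- seg$onset + seg$duration / 2
  comW <- sum((mid * seg$duration)[seg$label == "W"]) /
    sum(seg$duration[seg$label == "W"])
  comR <- sum((mid * seg$duration)[seg$label == "R"]) /
    sum(seg$duration[seg$label == "R"])
  expect_lt(comW, 9 * 3600 / 2)
  expect_gt(comR, 9 * 3600 / 2)
})

test_that("generated epoch counts match hypnogram stage durations exactly", {
  h <- generateHypnogram(defaultHypnogramModel(hours = 2), seed = 4)
  rec <- generateRecording(h, seed = 5)
  expect_equal(totalDuration(rec), totalDuration(h))
  m <- mapStages(h, stageConfig("five"))
  eps <- extractEpochs(rec, m)
  expect_equal(nEpochs(eps), sum(m$duration) / 30)
})

test_that("missing stage profiles are reported by name", {
  h <- hypnogram(0, 30, "4")
  prof <- defaultStageProfiles()
  prof[["4"]] <- NULL
  expect_error(generateRecording(h, profiles = prof, seed = 1), "'4'")
})

test_that("wake EEG peaks in the alpha band", {
  h <- hypnogram(0, 300, "W")
  rec <- generateRecording(h, seed = 11)
  x <- channelData(rec, "EEG Fpz-Cz")[1:3000]
  p <- welchPsd(x, 100, fmin = 0.3, fmax = 40)
  fPeak <- p$freq[which.max(p$psd)]
  expect_gte(fPeak, 8)
  expect_lte(fPeak, 12)
})

test_that("wake EEG carries more total power than deep-sleep EEG", {
  rec <- stageBalancedRecording()
  m <- mapStages(stageBalancedHypnogram(), stageConfig("five"))
  eps <- extractEpochs(rec, m)
  for (ch in c("EEG Fpz-Cz", "EEG Pz-Oz")) {
    tot <- function(lbl) {
      idx <- which(epochLabels(eps) == lbl)
      mean(vapply(idx, function(e)
        sum(welchPsd(epochData(eps, e, ch), 100)$psd), numeric(1)))
    }
    expect_gt(tot("W"), tot("N3/N4"))
  }
})

test_that("REM with zero EMG tone has the quietest EMG channel", {
  prof <- defaultStageProfiles()
  prof$R$emg_tone <- 0
  h <- hypnogram(c(0, 30, 60, 90), rep(30, 4), c("2", "3", "R", "1"))
  rec <- generateRecording(h, profiles = prof, seed = 3)
  m <- mapStages(h, stageConfig("five"))
  eps <- extractEpochs(rec, m)
  vEmg <- vapply(seq_len(nEpochs(eps)), function(e)
    var(epochData(eps, e, "EMG submental")), numeric(1))
  remVar <- vEmg[epochLabels(eps) == "R"]
  expect_lt(max(remVar), min(vEmg[epochLabels(eps) != "R"]))
})

test_that("per-stage EEG band powers separate with margin over 50 epochs", {
  rec <- stageBalancedRecording()
  m <- mapStages(stageBalancedHypnogram(), stageConfig("five"))
  eps <- extractEpochs(rec, m)
  lab <- as.character(epochLabels(eps))
  bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
                sigma = c(12, 16))
  # stage designed to dominate each classical EEG band
  intended <- c(delta = "N3/N4", theta = "N2", alpha = "W", sigma = "N2")
  for (b in names(bands)) {
    pw <- vapply(seq_len(nEpochs(eps)), function(e)
      bandPower(epochData(eps, e, "EEG Fpz-Cz"), 100,
                bands[[b]][1], bands[[b]][2]), numeric(1))
    mu <- tapply(pw, lab, mean)
    se <- tapply(pw, lab, function(v) sd(v) / sqrt(length(v)))
    best <- intended[[b]]
    expect_identical(names(which.max(mu)), best,
                     label = paste("band", b))
    for (other in setdiff(names(mu), best))
      expect_gt(mu[[best]] - mu[[other]],
                3 * sqrt(se[[best]]^2 + se[[other]]^2),
                label = paste(b, ":", best, "vs", other))
  }
})

test_that("fixture datasets round-trip through EDF", {
  h <- hypnogram(c(0, 120, 210), c(120, 90, 90), c("W", "2", "R"))
  rec <- generateRecording(h, seed = 21)
  out <- withr::local_tempdir()
  paths <- writeFixtureDataset(rec, h, out)
  expect_true(all(file.exists(paths)))
  r2 <- readRecording(paths[["psg"]])
  h2 <- readHypnogram(paths[["hypnogram"]])
  expect_identical(channelNames(r2), channelNames(rec))
  expect_equal(unname(samplingRates(r2)), rep(100, 4))
  expect_identical(segments(h2)$label, segments(h)$label)
  expect_equal(sum(segments(h2)$duration), 300)
})

test_that("an empty recording is refused with no files written", {
  out <- withr::local_tempdir()
  empty <- psgRecording(list(), fs = numeric(0))
  expect_error(writeFixtureDataset(empty, hypnogram(0, 30, "W"), out),
               "empty")
  expect_length(list.files(out), 0)
})
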