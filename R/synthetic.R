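## Synthetic polysomnography: a stage-structured hypnogram simulator and a
## stage-conditioned signal generator. The generator emulates the statistical
## structure the staging pipeline relies on -- stage-dependent spectral
## content, EMG tone, EOG event rates, realistic stage-duration structure and
## severe class imbalance -- not physiological microstructure.

SIM_STAGES <- c("W", "1", "2", "3", "4", "R")

#' Default hypnogram model
#'
#' A first-order stage-transition model with geometric dwell times (in units
#' of 30-s epochs) and a time-inhomogeneous bias that favours wake early in
#' the night and REM late, reproducing the canonical overnight architecture:
#' wake skewed to the start, REM to the end, and stage 2 accumulating the
#' most total time.
#'
#' @param hours total recording duration in hours (default 9, the length of
#'   an overnight telemetry session).
#' @return A list with elements `transitionMatrix` (6x6, rows sum to 1, zero
#'   diagonal), `meanDwell` (seconds per stage), `initialStage`,
#'   `totalDuration` (s), `wakeBias` and `remBias` (functions of night
#'   fraction returning probability multipliers).
#' @export
defaultHypnogramModel <- function(hours = 9) {
  tm <- rbind(
    W = c(W = 0,   `1` = 0.65, `2` = 0.25, `3` = 0.03, `4` = 0.02, R = 0.05),
    `1` = c(0.15, 0,    0.65, 0.05, 0,    0.15),
    `2` = c(0.07, 0.13, 0,    0.35, 0.10, 0.35),
    `3` = c(0.05, 0.03, 0.35, 0,    0.50, 0.07),
    `4` = c(0.05, 0.02, 0.28, 0.60, 0,    0.05),
    R = c(0.25, 0.30, 0.40, 0.05, 0,    0))
  colnames(tm) <- SIM_STAGES
  list(
    transitionMatrix = tm,
    meanDwell = c(W = 120, `1` = 60, `2` = 330, `3` = 240, `4` = 210, R = 300),
    initialStage = "W",
    totalDuration = round(hours * 3600 / 30) * 30,
    wakeBias = function(t) 0.25 + 2.5 * exp(-4 * t),
    remBias = function(t) 0.10 + 2.2 * t)
}

validateHypnogramModel <- function(model) {
  tm <- model$transitionMatrix
  if (!is.matrix(tm) || nrow(tm) != ncol(tm))
    stop("invalid hypnogram model: transition matrix must be square")
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-8))
    stop("invalid hypnogram model: transition-matrix rows must be ",
         "non-negative and sum to 1")
  if (any(model$meanDwell < 30))
    stop("invalid hypnogram model: mean dwell times must be >= 30 s")
  if (model$totalDuration %% 30 != 0)
    stop("invalid hypnogram model: total duration must be a multiple of 30 s")
  if (!model$initialStage %in% rownames(tm))
    stop("invalid hypnogram model: unknown initial stage ",
         sQuote(model$initialStage))
  invisible(model)
}

#' Simulate an overnight hypnogram
#'
#' Draws stage segments from the model's transition matrix with geometric
#' dwell times (multiples of 30 s) and the model's early-wake / late-REM
#' bias. Identical seeds yield identical hypnograms.
#'
#' @param model a hypnogram model, see [defaultHypnogramModel()].
#' @param seed integer RNG seed.
#' @return A [Hypnogram-class] covering `model$totalDuration` seconds.
#' @examples
#' hyp <- generateHypnogram(defaultHypnogramModel(hours = 2), seed = 1)
#' segments(hyp)[1:3, ]
#' @export
generateHypnogram <- function(model = defaultHypnogramModel(), seed = 1) {
  validateHypnogramModel(model)
  stages <- rownames(model$transitionMatrix)
  withr::with_seed(as.integer(seed), {
    nTotal <- model$totalDuration / 30
    lab <- character(0); dur <- numeric(0)
    stage <- model$initialStage
    used <- 0
    while (used < nTotal) {
      mdw <- model$meanDwell[[stage]] / 30
      nEp <- 1L + stats::rgeom(1L, prob = min(1, 1 / mdw))
      nEp <- min(nEp, nTotal - used)
      lab <- c(lab, stage); dur <- c(dur, nEp * 30)
      used <- used + nEp
      if (used >= nTotal) break
      p <- model$transitionMatrix[stage, ]
      tfrac <- used / nTotal
      if (!is.null(model$wakeBias) && "W" %in% stages)
        p[["W"]] <- p[["W"]] * model$wakeBias(tfrac)
      if (!is.null(model$remBias) && "R" %in% stages)
        p[["R"]] <- p[["R"]] * model$remBias(tfrac)
      if (sum(p) <= 0) break   # absorbing stage: dwell to the end
      stage <- sample(stages, 1L, prob = p / sum(p))
    }
    if (used < nTotal) {  # absorbing chain: extend last segment
      dur[length(dur)] <- dur[length(dur)] + (nTotal - used) * 30
    }
    ## merge consecutive identical stages (possible after truncation)
    keep <- c(TRUE, lab[-1L] != lab[-length(lab)])
    grp <- cumsum(keep)
    dur <- as.numeric(tapply(dur, grp, sum))
    lab <- lab[keep]
    hypnogram(onset = cumsum(c(0, dur[-length(dur)])), duration = dur,
              label = lab)
  })
}

#' Default stage signal profiles
#'
#' Textbook spectral signatures per stage: wake has a strong 10-Hz alpha
#' rhythm with high EMG tone, N1 low-amplitude 5-Hz theta, N2 theta plus
#' 13-Hz spindle bursts (1-s, Poisson 3/min), N3/N4 high-amplitude slow
#' delta (1.5 and 1.2 Hz), REM low-amplitude mixed 3/6-Hz activity with
#' near-atonic EMG and frequent EOG deflections. Amplitudes are in the
#' recording's physical units (microvolts).
#'
#' @return Named list of per-stage profiles. Each profile has: `bands`
#'   (matrix with columns freq, bw, amp applied to the EEG channels),
#'   `noise_sd` (named broadband noise SD per channel), `emg_tone` (EMG SD),
#'   `eog_rate` (events/min), `eog_amp`, and optionally `spindle`
#'   (freq, amp, rate_per_min, dur).
#' @export
defaultStageProfiles <- function() {
  band <- function(...) matrix(c(...), ncol = 3, byrow = TRUE,
                               dimnames = list(NULL, c("freq", "bw", "amp")))
  noise <- function(eeg, eog) c("EEG Fpz-Cz" = eeg, "EEG Pz-Oz" = eeg,
                                "EOG horizontal" = eog)
  list(
    W = list(bands = band(10, 2, 65), noise_sd = noise(15, 15),
             emg_tone = 25, eog_rate = 5, eog_amp = 60),
    `1` = list(bands = band(5, 2, 25), noise_sd = noise(10, 10),
               emg_tone = 10, eog_rate = 2, eog_amp = 40),
    `2` = list(bands = band(5, 2, 30), noise_sd = noise(10, 8),
               emg_tone = 8, eog_rate = 0.5, eog_amp = 40,
               spindle = list(freq = 13, amp = 40, rate_per_min = 3,
                              dur = 1)),
    `3` = list(bands = band(1.5, 0.8, 50), noise_sd = noise(8, 6),
               emg_tone = 5, eog_rate = 0.2, eog_amp = 40),
    `4` = list(bands = band(1.2, 0.6, 58), noise_sd = noise(8, 6),
               emg_tone = 4, eog_rate = 0.2, eog_amp = 40),
    R = list(bands = band(3, 1.5, 12, 6, 2, 12), noise_sd = noise(8, 10),
             emg_tone = 0.8, eog_rate = 8, eog_amp = 80))
}

## One 30-s epoch of all four channels for a given stage profile.
synthEpochChannels <- function(profile, fs, nSamp) {
  t <- seq_len(nSamp) / fs
  eegBand <- function(scale) {
    sig <- numeric(nSamp)
    b <- profile$bands
    for (i in seq_len(nrow(b))) {
      f <- stats::runif(1, b[i, "freq"] - b[i, "bw"] / 2,
                        b[i, "freq"] + b[i, "bw"] / 2)
      sig <- sig + scale * b[i, "amp"] *
        sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
    }
    if (!is.null(profile$spindle)) {
      sp <- profile$spindle
      nb <- stats::rpois(1, sp$rate_per_min * nSamp / fs / 60)
      for (j in seq_len(nb)) {
        len <- round(sp$dur * fs)
        start <- sample.int(max(1L, nSamp - len), 1L)
        idx <- start:(start + len - 1L)
        env <- 0.5 * (1 - cos(2 * pi * seq_len(len) / len))   # Hann burst
        sig[idx] <- sig[idx] + scale * sp$amp * env *
          sin(2 * pi * sp$freq * (idx / fs) + stats::runif(1, 0, 2 * pi))
      }
    }
    sig
  }
  eog <- stats::rnorm(nSamp, 0, profile$noise_sd[["EOG horizontal"]])
  nEv <- stats::rpois(1, profile$eog_rate * nSamp / fs / 60)
  for (j in seq_len(nEv)) {
    len <- round(stats::runif(1, 0.4, 0.8) * fs)     # square deflection
    start <- sample.int(max(1L, nSamp - len), 1L)
    eog[start:(start + len - 1L)] <- eog[start:(start + len - 1L)] +
      sample(c(-1, 1), 1L) * profile$eog_amp
  }
  list(
    "EEG Fpz-Cz" = eegBand(1) +
      stats::rnorm(nSamp, 0, profile$noise_sd[["EEG Fpz-Cz"]]),
    "EEG Pz-Oz" = eegBand(0.75) +
      stats::rnorm(nSamp, 0, profile$noise_sd[["EEG Pz-Oz"]]),
    "EOG horizontal" = eog,
    "EMG submental" = stats::rnorm(nSamp, 0, profile$emg_tone))
}

#' Synthesize a multi-channel PSG recording from a hypnogram
#'
#' Generates the four canonical channels (`EEG Fpz-Cz`, `EEG Pz-Oz`,
#' `EOG horizontal`, `EMG submental`) epoch by epoch, drawing each 30-s
#' window's content from the profile of that epoch's stage. Identical seeds
#' yield bit-identical signals.
#'
#' @param hyp a [Hypnogram-class].
#' @param profiles named list of stage profiles, see
#'   [defaultStageProfiles()].
#' @param fs sampling rate in Hz (default 100, the telemetry convention;
#'   must exceed twice the highest profile frequency).
#' @param seed integer RNG seed.
#' @return A [PSGRecording-class] with all channels at `fs`.
#' @examples
#' hyp <- hypnogram(0, 60, "W")
#' rec <- generateRecording(hyp, seed = 1)
#' channelNames(rec)
#' @export
generateRecording <- function(hyp, profiles = defaultStageProfiles(),
                              fs = 100, seed = 1) {
  seg <- segments(hyp)
  missing <- setdiff(unique(seg$label), names(profiles))
  if (length(missing))
    stop("no signal profile for stage(s): ",
         paste(sQuote(missing), collapse = ", "))
  fmax <- max(vapply(profiles, function(p) {
    m <- max(p$bands[, "freq"] + p$bands[, "bw"] / 2)
    if (!is.null(p$spindle)) m <- max(m, p$spindle$freq)
    m
  }, numeric(1)))
  if (fs <= 2 * fmax)
    stop("fs must exceed twice the highest profile frequency (",
         fmax, " Hz)")
  nSamp <- round(30 * fs)
  nTotal <- round(sum(seg$duration) * fs)
  sig <- lapply(PSG_CHANNELS, function(ch) numeric(nTotal))
  names(sig) <- PSG_CHANNELS
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(nrow(seg))) {
      nEp <- round(seg$duration[i] / 30)
      prof <- profiles[[seg$label[i]]]
      for (e in seq_len(nEp)) {
        off <- round((seg$onset[i] + (e - 1) * 30) * fs)
        ep <- synthEpochChannels(prof, fs, nSamp)
        for (ch in PSG_CHANNELS)
          sig[[ch]][off + seq_len(nSamp)] <- ep[[ch]]
      }
    }
  })
  psgRecording(sig, fs = fs)
}

#' Simulate a complete synthetic PSG session
#'
#' Convenience wrapper: hypnogram plus matching recording.
#'
#' @param hours session length in hours.
#' @param seed integer RNG seed (hypnogram and signals derive sub-seeds
#'   from it).
#' @param profiles stage profiles, see [defaultStageProfiles()].
#' @param fs sampling rate (Hz).
#' @return List with elements `recording` and `hypnogram`.
#' @export
simulatePsg <- function(hours = 9, seed = 1,
                        profiles = defaultStageProfiles(), fs = 100) {
  seed <- as.integer(seed)
  hyp <- generateHypnogram(defaultHypnogramModel(hours), seed = seed)
  rec <- generateRecording(hyp, profiles = profiles, fs = fs,
                           seed = seed + 1000L)
  list(recording = rec, hypnogram = hyp)
}

#' Write a synthetic session as EDF fixtures
#'
#' Persists the recording as an EDF signal file and the hypnogram as an
#' EDF+ annotation file using the sleep-edfx label spellings
#' (`"Sleep stage W"`, ...), so synthetic and real data share one reader.
#'
#' @param recording a [PSGRecording-class].
#' @param hyp a [Hypnogram-class].
#' @param outDir output directory (created if absent).
#' @param name file stem (default `"synthetic"`, files
#'   `<name>-PSG.edf` / `<name>-Hypnogram.edf`).
#' @return Named character vector with paths `psg` and `hypnogram`.
#' @export
writeFixtureDataset <- function(recording, hyp, outDir, name = "synthetic") {
  if (!is(recording, "PSGRecording") || !length(recording@signals) ||
      totalDuration(recording) <= 0)
    stop("empty recording: nothing to write")
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  psgPath <- file.path(outDir, paste0(name, "-PSG.edf"))
  hypPath <- file.path(outDir, paste0(name, "-Hypnogram.edf"))
  writeRecordingEdf(recording, psgPath)
  writeHypnogramEdf(hyp, hypPath, startTime = recording@startTime)
  c(psg = psgPath, hypnogram = hypPath)
}
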