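## Central data containers for the sleep-staging pipeline.

#' Raw Rechtschaffen--Kales stage labels
#'
#' The eight raw hypnogram labels: wake, stages 1--4, REM, movement time
#' and not-scored.
#' @export
RAW_STAGE_LABELS <- c("W", "1", "2", "3", "4", "R", "M", "?")

## Required polysomnography channels, in the fixed pipeline order.
#' Canonical PSG channel labels used by the pipeline
#' @export
PSG_CHANNELS <- c("EEG Fpz-Cz", "EEG Pz-Oz", "EOG horizontal",
                  "EMG submental")

# ---------------------------------------------------------------------------
# PSGRecording
# ---------------------------------------------------------------------------

#' Multi-channel polysomnography recording
#'
#' Holds sampled signals together with channel labels, per-channel sampling
#' rates and physical units. Channels may have different sampling rates but
#' must describe a common duration.
#'
#' @slot signals named list of numeric vectors, one per channel.
#' @slot fs named numeric vector of sampling rates (Hz).
#' @slot units named character vector of physical units.
#' @slot startTime POSIXct recording start.
#'
#' @export
setClass("PSGRecording",
  representation(signals = "list", fs = "numeric", units = "character",
                 startTime = "POSIXct"),
  validity = function(object) {
    msg <- character()
    labs <- names(object@signals)
    if (length(object@signals) && (is.null(labs) || any(labs == "")))
      msg <- c(msg, "all channels must be named")
    if (length(object@signals) && !identical(labs, names(object@fs)))
      msg <- c(msg, "names of 'signals' and 'fs' must match")
    if (any(object@fs <= 0)) msg <- c(msg, "sampling rates must be > 0")
    durs <- vapply(seq_along(object@signals),
                   function(i) length(object@signals[[i]]) / object@fs[[i]],
                   numeric(1))
    if (length(durs) > 1L && diff(range(durs)) > 1e-6)
      msg <- c(msg, "channels imply inconsistent recording durations")
    if (length(msg)) msg else TRUE
  })

#' Construct a PSGRecording
#'
#' @param signals named list of numeric sample vectors.
#' @param fs sampling rate(s) in Hz; recycled across channels if scalar.
#' @param units physical units per channel (default `"uV"`).
#' @param startTime recording start time.
#' @return A [PSGRecording-class] object.
#' @examples
#' rec <- psgRecording(list("EEG Fpz-Cz" = sin(seq_len(3000) / 10)), fs = 100)
#' samplingRates(rec)
#' @export
psgRecording <- function(signals, fs, units = "uV",
                         startTime = as.POSIXct("2000-01-01", tz = "UTC")) {
  labs <- names(signals)
  fs <- rep_len(fs, length(signals))
  units <- rep_len(units, length(signals))
  names(fs) <- labs
  names(units) <- labs
  new("PSGRecording", signals = signals, fs = fs, units = units,
      startTime = startTime)
}

#' @rdname channelNames
#' @export
setMethod("channelNames", "PSGRecording", function(x) names(x@signals))

#' @rdname samplingRates
#' @export
setMethod("samplingRates", "PSGRecording", function(x) x@fs)

#' @rdname channelData
#' @export
setMethod("channelData", "PSGRecording", function(x, channel) {
  if (is.character(channel) && !channel %in% names(x@signals))
    stop("no such channel: '", channel, "'")
  x@signals[[channel]]
})

#' @rdname totalDuration
#' @export
setMethod("totalDuration", "PSGRecording", function(x) {
  if (!length(x@signals)) return(0)
  length(x@signals[[1L]]) / x@fs[[1L]]
})

setMethod("show", "PSGRecording", function(object) {
  cat("PSGRecording:", length(object@signals), "channel(s),",
      sprintf("%.0f s\n", totalDuration(object)))
  for (ch in names(object@signals))
    cat(sprintf("  %-16s %6.1f Hz  [%s]\n", ch, object@fs[[ch]],
                object@units[[ch]]))
})

# ---------------------------------------------------------------------------
# Hypnogram
# ---------------------------------------------------------------------------

#' Expert-scored hypnogram
#'
#' Time-ordered, non-overlapping stage annotations. Segment times are
#' seconds from recording start; intervals are half-open
#' `[onset, onset + duration)`.
#'
#' @slot onset numeric vector of segment onsets (s).
#' @slot duration numeric vector of segment durations (s).
#' @slot label character vector of raw stage labels
#'   (one of `W,1,2,3,4,R,M,?`).
#'
#' @export
setClass("Hypnogram",
  representation(onset = "numeric", duration = "numeric",
                 label = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@onset)
    if (length(object@duration) != n || length(object@label) != n)
      msg <- c(msg, "onset, duration and label must have equal length")
    if (any(object@duration <= 0)) msg <- c(msg, "durations must be > 0")
    bad <- setdiff(unique(object@label), RAW_STAGE_LABELS)
    if (length(bad))
      msg <- c(msg, paste0("unknown stage label(s): ",
                           paste(sQuote(bad), collapse = ", ")))
    if (n > 1L) {
      if (is.unsorted(object@onset, strictly = FALSE))
        msg <- c(msg, "segments must be time-ordered")
      ends <- object@onset + object@duration
      if (any(object@onset[-1L] < ends[-n] - 1e-9))
        msg <- c(msg, "segments must not overlap")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a Hypnogram
#'
#' @param onset segment onsets in seconds from recording start.
#' @param duration segment durations in seconds.
#' @param label raw stage labels in `W,1,2,3,4,R,M,?`.
#' @return A [Hypnogram-class] object.
#' @examples
#' hypnogram(c(0, 60, 120), c(60, 60, 30), c("W", "1", "2"))
#' @export
hypnogram <- function(onset, duration, label) {
  new("Hypnogram", onset = as.numeric(onset), duration = as.numeric(duration),
      label = as.character(label))
}

#' @rdname segments
#' @export
setMethod("segments", "Hypnogram", function(x) {
  data.frame(onset = x@onset, duration = x@duration, label = x@label,
             stringsAsFactors = FALSE)
})

#' @rdname totalDuration
#' @export
setMethod("totalDuration", "Hypnogram", function(x) sum(x@duration))

setMethod("show", "Hypnogram", function(object) {
  tot <- tapply(object@duration, object@label, sum)
  cat("Hypnogram:", length(object@onset), "segment(s),",
      sprintf("%.0f s total\n", sum(object@duration)))
  cat("  time per stage (s):",
      paste(names(tot), round(unname(tot)), sep = "=", collapse = " "), "\n")
})

# ---------------------------------------------------------------------------
# FilterKernel
# ---------------------------------------------------------------------------

#' Linear-phase FIR band-pass kernel
#'
#' @slot taps odd-length, symmetric impulse response.
#' @slot lFreq lower passband edge (Hz).
#' @slot hFreq upper passband edge (Hz).
#' @slot fs design sampling rate (Hz).
#' @slot lTrans,hTrans lower/upper transition bandwidths (Hz).
#' @slot designWindow window name (only `"hamming"` implemented).
#'
#' @export
setClass("FilterKernel",
  representation(taps = "numeric", lFreq = "numeric", hFreq = "numeric",
                 fs = "numeric", lTrans = "numeric", hTrans = "numeric",
                 designWindow = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@taps)
    if (n %% 2L == 0L) msg <- c(msg, "kernel length must be odd")
    if (max(abs(object@taps - rev(object@taps))) > 1e-12)
      msg <- c(msg, "kernel must be symmetric (linear phase)")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "FilterKernel", function(object) {
  cat(sprintf(
    "FilterKernel: %s-window FIR band-pass %.3g-%.3g Hz @ %g Hz, %d taps\n",
    object@designWindow, object@lFreq, object@hFreq, object@fs,
    length(object@taps)))
})

# ---------------------------------------------------------------------------
# EpochSet
# ---------------------------------------------------------------------------

#' Labelled 30-second PSG epochs
#'
#' @slot data numeric array `n_epochs x n_channels x samples_per_epoch`.
#' @slot labels factor of mapped class labels, one per epoch.
#' @slot rawLabels character vector of raw stage labels per epoch.
#' @slot channels channel labels (dimension 2 of `data`).
#' @slot fs common sampling rate (Hz).
#' @slot epochLen epoch length in seconds (30 by default).
#'
#' @export
setClass("EpochSet",
  representation(data = "array", labels = "factor", rawLabels = "character",
                 channels = "character", fs = "numeric", epochLen = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3L) msg <- c(msg, "data must be a 3-d array")
    else {
      if (d[1L] != length(object@labels))
        msg <- c(msg, "one label per epoch required")
      if (d[1L] != length(object@rawLabels))
        msg <- c(msg, "one raw label per epoch required")
      if (d[2L] != length(object@channels))
        msg <- c(msg, "channel labels must match dim 2")
      if (abs(d[3L] - object@epochLen * object@fs) > 1e-9)
        msg <- c(msg, "samples per epoch must equal epochLen * fs")
    }
    if (length(msg)) msg else TRUE
  })

#' @rdname nEpochs
#' @export
setMethod("nEpochs", "EpochSet", function(x) dim(x@data)[1L])

#' @rdname epochLabels
#' @export
setMethod("epochLabels", "EpochSet", function(x) x@labels)

#' @rdname rawLabels
#' @export
setMethod("rawLabels", "EpochSet", function(x) x@rawLabels)

#' @rdname channelNames
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channels)

#' Extract one epoch-channel series from an EpochSet
#'
#' @param x an [EpochSet-class] object.
#' @param epoch epoch index.
#' @param channel channel label or index.
#' @return Numeric vector of samples.
#' @export
epochData <- function(x, epoch, channel) {
  stopifnot(is(x, "EpochSet"))
  if (is.character(channel)) channel <- match(channel, x@channels)
  as.numeric(x@data[epoch, channel, ])
}

setMethod("show", "EpochSet", function(object) {
  cat("EpochSet:", nEpochs(object), "epochs x", length(object@channels),
      "channels x", dim(object@data)[3L], "samples",
      sprintf("(%g s @ %g Hz)\n", object@epochLen, object@fs))
  print(table(object@labels))
})

# ---------------------------------------------------------------------------
# SleepFeatureTable
# ---------------------------------------------------------------------------

#' Epoch feature table
#'
#' A \linkS4class{SummarizedExperiment} with one assay `"features"`
#' (features in rows, epochs in columns), the mapped class label and the
#' raw stage label in `colData`. Feature names follow
#' `"{channel}::{measure}[::{bin}]"`.
#'
#' @export
setClass("SleepFeatureTable",
  contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- character()
    if (!"features" %in% SummarizedExperiment::assayNames(object))
      msg <- c(msg, "assay 'features' is required")
    else {
      m <- SummarizedExperiment::assay(object, "features")
      if (any(!is.finite(m)))
        msg <- c(msg, "feature values must be finite (no NaN/Inf)")
      if (anyDuplicated(rownames(m)))
        msg <- c(msg, "feature names must be unique")
    }
    if (!"label" %in% colnames(SummarizedExperiment::colData(object)))
      msg <- c(msg, "colData must contain a 'label' column")
    if (length(msg)) msg else TRUE
  })

#' Construct a SleepFeatureTable from an epochs-by-features matrix
#'
#' @param values numeric matrix, one row per epoch, named feature columns.
#' @param labels class label per epoch (coerced to factor).
#' @param rawLabels optional raw stage label per epoch.
#' @return A [SleepFeatureTable-class] object.
#' @export
sleepFeatureTable <- function(values, labels, rawLabels = NULL) {
  values <- as.matrix(values)
  labels <- as.factor(labels)
  if (is.null(rawLabels)) rawLabels <- rep(NA_character_, nrow(values))
  if (is.null(rownames(values)) && nrow(values) > 0L)
    rownames(values) <- paste0("epoch_", seq_len(nrow(values)))
  cd <- S4Vectors::DataFrame(label = labels,
                             rawLabel = as.character(rawLabels),
                             row.names = rownames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(values)), colData = cd)
  new("SleepFeatureTable", se)
}

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "SleepFeatureTable", function(x)
  t(SummarizedExperiment::assay(x, "features")))

#' @rdname featureNames
#' @export
setMethod("featureNames", "SleepFeatureTable", function(x) rownames(x))

#' @rdname nEpochs
#' @export
setMethod("nEpochs", "SleepFeatureTable", function(x) ncol(x))

#' @rdname epochLabels
#' @export
setMethod("epochLabels", "SleepFeatureTable", function(x)
  SummarizedExperiment::colData(x)$label)

#' @rdname rawLabels
#' @export
setMethod("rawLabels", "SleepFeatureTable", function(x)
  SummarizedExperiment::colData(x)$rawLabel)

setMethod("show", "SleepFeatureTable", function(object) {
  cat("SleepFeatureTable:", ncol(object), "epochs x", nrow(object),
      "features\n")
  print(table(epochLabels(object)))
})

# ---------------------------------------------------------------------------
# EvaluationReport
# ---------------------------------------------------------------------------

#' Classifier evaluation report
#'
#' Per-class and overall hold-out metrics plus (optionally) averaged
#' cross-validation metrics. Percentages are stored as fractions and
#' printed to two decimals.
#'
#' @slot confusion class-by-class count matrix (rows = truth).
#' @slot perClass data.frame with precision, recall, f1 (fractions) and
#'   support per class.
#' @slot accuracy overall hold-out accuracy (fraction).
#' @slot macroAUC macro one-vs-rest AUC (fraction; NA if unavailable).
#' @slot cv data.frame of per-fold CV metrics (zero rows if CV not run).
#' @slot meta list of run parameters (seeds, SMOTE placement, learner, ...).
#'
#' @export
setClass("EvaluationReport",
  representation(confusion = "matrix", perClass = "data.frame",
                 accuracy = "numeric", macroAUC = "numeric",
                 cv = "data.frame", meta = "list"),
  validity = function(object) {
    msg <- character()
    cm <- object@confusion
    if (nrow(cm) != ncol(cm)) msg <- c(msg, "confusion matrix must be square")
    if (nrow(object@perClass) &&
        !isTRUE(all.equal(unname(rowSums(cm)),
                          unname(object@perClass$support))))
      msg <- c(msg, "confusion-matrix row sums must equal class supports")
    if (length(msg)) msg else TRUE
  })

#' Confusion matrix of an evaluation report
#' @param report an [EvaluationReport-class] object.
#' @return Class-by-class count matrix, rows are true classes.
#' @export
confusionMatrix <- function(report) report@confusion

#' Per-class metrics of an evaluation report
#' @param report an [EvaluationReport-class] object.
#' @return data.frame with class, precision, recall, f1 (fractions), support.
#' @export
perClassMetrics <- function(report) report@perClass

#' Overall hold-out accuracy (fraction)
#' @param report an [EvaluationReport-class] object.
#' @return Accuracy as a fraction in [0, 1].
#' @export
overallAccuracy <- function(report) report@accuracy

#' Averaged cross-validation metrics
#' @param report an [EvaluationReport-class] object.
#' @return Named numeric vector with mean accuracy, recall, precision and
#'   AUC over folds, or NULL if cross-validation was not run.
#' @export
cvSummary <- function(report) {
  if (!nrow(report@cv)) return(NULL)
  colMeans(report@cv[, c("accuracy", "recall", "precision", "auc")],
           na.rm = TRUE)
}

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  cat(sprintf("  hold-out accuracy: %.2f%%", 100 * object@accuracy))
  if (is.finite(object@macroAUC))
    cat(sprintf("   macro AUC: %.4f", object@macroAUC))
  cat("\n  per-class metrics (%):\n")
  pc <- object@perClass
  for (i in seq_len(nrow(pc)))
    cat(sprintf("    %-10s precision %6.2f  recall %6.2f  F1 %6.2f  n=%d\n",
                pc$class[i], 100 * pc$precision[i], 100 * pc$recall[i],
                100 * pc$f1[i], pc$support[i]))
  if (nrow(object@cv)) {
    cv <- cvSummary(object)
    cat(sprintf(
      "  CV over %d folds: acc %.2f%%  recall %.2f%%  prec %.2f%%  AUC %.4f\n",
      nrow(object@cv), 100 * cv["accuracy"], 100 * cv["recall"],
      100 * cv["precision"], cv["auc"]))
  }
})
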