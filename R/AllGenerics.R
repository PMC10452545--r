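#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats fft rnorm runif rgeom rpois sd var lm coef predict
#'   quantile rbinom
#' @importFrom utils head read.csv write.csv
NULL

#' Channel labels of a recording or epoch set
#'
#' @param x a [PSGRecording-class] or [EpochSet-class] object.
#' @return Character vector of channel labels, in stored order.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Per-channel sampling rates (Hz)
#'
#' @param x a [PSGRecording-class] object.
#' @return Named numeric vector of sampling rates.
#' @export
setGeneric("samplingRates", function(x) standardGeneric("samplingRates"))

#' Signal samples of one channel
#'
#' @param x a [PSGRecording-class] object.
#' @param channel channel label or index.
#' @return Numeric vector of samples.
#' @export
setGeneric("channelData", function(x, channel) standardGeneric("channelData"))

#' Recording duration in seconds
#'
#' @param x a [PSGRecording-class] or [Hypnogram-class] object.
#' @return Duration in seconds.
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))

#' Hypnogram segments
#'
#' @param x a [Hypnogram-class] object.
#' @return `data.frame` with columns `onset`, `duration`, `label`
#'   (seconds from recording start; half-open intervals).
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' Number of epochs
#'
#' @param x an [EpochSet-class] or [SleepFeatureTable-class] object.
#' @return Integer count of 30-s epochs.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' Per-epoch class labels
#'
#' @param x an [EpochSet-class] or [SleepFeatureTable-class] object.
#' @return Factor of class labels, one per epoch.
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))

#' Per-epoch raw stage labels
#'
#' Raw Rechtschaffen--Kales labels (`W,1,2,3,4,R`) kept alongside the
#' mapped class labels so a feature table can be re-labelled under a
#' different stage configuration without recomputing features.
#'
#' @param x an [EpochSet-class] or [SleepFeatureTable-class] object.
#' @return Character vector of raw stage labels.
#' @export
setGeneric("rawLabels", function(x) standardGeneric("rawLabels"))

#' Epochs-by-features matrix
#'
#' @param x a [SleepFeatureTable-class] object.
#' @return Numeric matrix with one row per epoch and one named column per
#'   feature.
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' Feature names
#'
#' @param x a [SleepFeatureTable-class] object.
#' @return Character vector of feature names
#'   (`"{channel}::{measure}[::{bin}]"`).
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))
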