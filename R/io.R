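## High-level PSG input/output: recordings, hypnograms, feature tables.

#' Read a PSG recording from an EDF file
#'
#' Returns every stored sample signal with its label, sampling rate and
#' physical unit; nothing is resampled or dropped. Absence of the four
#' canonical pipeline channels is flagged later, at epoch extraction.
#'
#' @param path an EDF/EDF+ signal file.
#' @return A [PSGRecording-class].
#' @export
readRecording <- function(path) {
  edf <- readEdf(path)
  if (!length(edf$signals))
    stop("no sample signals in ", path, " (annotation-only file?)")
  psgRecording(edf$signals, fs = edf$fs, units = edf$units,
               startTime = edf$startTime)
}

## Normalisation table for raw stage labels: sleep-edfx spellings and bare
## letters are both accepted so real and synthetic files share one reader.
normalizeStageLabels <- function(x) {
  map <- c("Sleep stage W" = "W", "Sleep stage 1" = "1",
           "Sleep stage 2" = "2", "Sleep stage 3" = "3",
           "Sleep stage 4" = "4", "Sleep stage R" = "R",
           "Sleep stage ?" = "?", "Movement time" = "M",
           "Sleep stage M" = "M",
           W = "W", `1` = "1", `2` = "2", `3` = "3", `4` = "4", R = "R",
           M = "M", `?` = "?")
  x <- trimws(x)
  out <- map[x]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown stage label(s): ", paste(sQuote(bad), collapse = ", "))
  }
  unname(out)
}

#' Read a hypnogram from an EDF+ annotation file
#'
#' Parses the time-stamped annotation lists, normalises labels to the raw
#' alphabet `W,1,2,3,4,R,M,?` and returns time-ordered, non-overlapping
#' segments. Unknown label strings raise an error naming the label.
#'
#' @param path an EDF+ file carrying stage annotations (e.g. a sleep-edfx
#'   `*-Hypnogram.edf` file or one written by [writeHypnogramEdf()]).
#' @return A [Hypnogram-class].
#' @export
readHypnogram <- function(path) {
  edf <- readEdf(path)
  ann <- edf$annotations
  if (!nrow(ann)) stop("no annotations found in ", path)
  ann <- ann[!is.na(ann$duration) & ann$duration > 0, , drop = FALSE]
  ann <- ann[order(ann$onset), , drop = FALSE]
  hypnogram(onset = ann$onset, duration = ann$duration,
            label = normalizeStageLabels(ann$annotation))
}

#' Persist a feature table as CSV
#'
#' UTF-8, header row, RFC-4180 quoting; one row per epoch, feature columns
#' first, then `label` and `rawLabel`. Values round-trip within
#' floating-point text precision.
#'
#' @param table a [SleepFeatureTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureTable <- function(table, path) {
  stopifnot(is(table, "SleepFeatureTable"))
  df <- as.data.frame(featureMatrix(table), check.names = FALSE)
  df$label <- as.character(epochLabels(table))
  df$rawLabel <- rawLabels(table)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a feature table written by [writeFeatureTable()]
#'
#' @param path CSV path.
#' @param requiredFeatures optional character vector; an error listing the
#'   missing columns is raised if any are absent.
#' @return A [SleepFeatureTable-class].
#' @export
readFeatureTable <- function(path, requiredFeatures = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (!"label" %in% colnames(df))
    stop("schema mismatch: missing columns: label")
  if (!is.null(requiredFeatures)) {
    missing <- setdiff(requiredFeatures, colnames(df))
    if (length(missing))
      stop("schema mismatch: missing columns: ",
           paste(missing, collapse = ", "))
  }
  labels <- df$label
  rawLab <- if ("rawLabel" %in% colnames(df)) df$rawLabel else NULL
  feat <- df[, setdiff(colnames(df), c("label", "rawLabel")), drop = FALSE]
  values <- as.matrix(feat)
  if (nrow(values) == 0L)
    values <- matrix(numeric(0), nrow = 0, ncol = ncol(feat),
                     dimnames = list(NULL, colnames(feat)))
  sleepFeatureTable(values, labels = labels, rawLabels = rawLab)
}
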