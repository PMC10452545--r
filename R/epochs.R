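## Segmentation of annotated recordings into labelled 30-s epochs.

#' Extract labelled epochs from a recording
#'
#' Cuts one epoch per full `epochLen`-second window inside each mapped
#' segment; partial trailing windows are discarded. Channels are stored in
#' the fixed canonical order (`EEG Fpz-Cz`, `EEG Pz-Oz`, `EOG horizontal`,
#' `EMG submental`); a missing required channel raises an error naming it.
#' The recording is expected to be filtered already -- epochs are plain
#' slices, never re-filtered.
#'
#' @param recording a [PSGRecording-class] (all required channels at one
#'   common sampling rate).
#' @param mappedSegments `data.frame` from [mapStages()] with columns
#'   `onset`, `duration`, `class`, `raw`.
#' @param epochLen epoch length in seconds (default 30).
#' @param classes optional class levels for the label factor.
#' @return An [EpochSet-class]; empty (zero epochs) if no labelled segments
#'   yield a full window.
#' @export
extractEpochs <- function(recording, mappedSegments, epochLen = 30,
                          classes = NULL) {
  missing <- setdiff(PSG_CHANNELS, channelNames(recording))
  if (length(missing))
    stop("missing required channel(s): ",
         paste(sQuote(missing), collapse = ", "))
  fs <- unique(unname(recording@fs[PSG_CHANNELS]))
  if (length(fs) != 1L)
    stop("required channels must share one sampling rate")
  nSamp <- round(epochLen * fs)
  seg <- mappedSegments
  nPer <- if (nrow(seg)) floor(seg$duration / epochLen) else integer(0)
  nEp <- sum(nPer)
  if (is.null(classes)) classes <- unique(seg$class)
  data <- array(0, dim = c(nEp, length(PSG_CHANNELS), nSamp))
  labels <- character(nEp); raws <- character(nEp)
  totalSamples <- if (nEp) length(channelData(recording, PSG_CHANNELS[1L]))
                  else 0L
  e <- 0L
  for (i in seq_len(nrow(seg))) {
    for (k in seq_len(nPer[i])) {
      off <- round((seg$onset[i] + (k - 1) * epochLen) * fs)
      if (off + nSamp > totalSamples)
        stop("segment at ", seg$onset[i], " s extends past the recording")
      e <- e + 1L
      labels[e] <- seg$class[i]
      raws[e] <- seg$raw[i]
      for (ci in seq_along(PSG_CHANNELS))
        data[e, ci, ] <- recording@signals[[PSG_CHANNELS[ci]]][
          off + seq_len(nSamp)]
    }
  }
  new("EpochSet", data = data,
      labels = factor(labels, levels = classes),
      rawLabels = raws, channels = PSG_CHANNELS, fs = fs,
      epochLen = epochLen)
}
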