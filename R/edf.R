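## Minimal European Data Format (EDF/EDF+) reader and writer.
##
## Implements the subset of the format the pipeline needs: fixed-rate
## sample signals (16-bit, little-endian) and EDF+ time-stamped annotation
## lists (TALs) for hypnograms. Only continuous ("EDF+C") layouts are
## handled; signals are returned unresampled in physical units.

EDF_HEADER_BYTES <- 256L

padField <- function(x, width) {
  x <- as.character(x)
  if (nchar(x, type = "bytes") > width)
    stop("EDF header field too long: ", sQuote(x))
  formatC(x, width = width, flag = "-")
}

## EDF numeric fields are ASCII; avoid scientific notation and trailing zeros.
edfNum <- function(x, width) {
  s <- sub("\\.?0+$", "", sprintf("%.4f", x))
  if (nchar(s) > width) s <- substr(s, 1, width)
  padField(s, width)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over each channel's observed
#' physical range (symmetric around zero), using 1-s data records.
#'
#' @param recording a [PSGRecording-class]; all channels must have integer
#'   samples-per-second rates.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeRecordingEdf <- function(recording, path) {
  stopifnot(is(recording, "PSGRecording"))
  sig <- recording@signals
  ns <- length(sig)
  fs <- recording@fs
  if (any(abs(fs - round(fs)) > 1e-9))
    stop("EDF writer requires integer samples per 1-s record")
  nRec <- as.integer(round(totalDuration(recording)))
  if (nRec < 1) stop("empty recording: nothing to write")

  physMax <- vapply(sig, function(x) max(abs(x), 1e-6), numeric(1)) * 1.001
  digMax <- 32767
  dig <- lapply(seq_len(ns), function(i) {
    v <- as.integer(round(sig[[i]] / physMax[i] * digMax))
    length(v) <- nRec * round(fs[i])   # pad trailing partial second with NA
    v[is.na(v)] <- 0L
    v
  })

  st <- as.POSIXlt(recording@startTime)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8), padField("X X X X", 80),
    padField("Startdate X X X X", 80),
    padField(sprintf("%02d.%02d.%02d", st$mday, st$mon + 1L,
                     st$year %% 100), 8),
    padField(sprintf("%02d.%02d.%02d", st$hour, st$min,
                     floor(st$sec)), 8),
    padField(EDF_HEADER_BYTES * (ns + 1L), 8),
    padField("EDF+C", 44), padField(nRec, 8), padField(1, 8),
    padField(ns, 4))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  field <- function(values, width)
    writeChar(paste0(vapply(values, padField, "", width = width),
                     collapse = ""), con, eos = NULL, useBytes = TRUE)
  field(names(sig), 16)
  field(rep("", ns), 80)
  field(unname(recording@units), 8)
  writeChar(paste0(vapply(-physMax, edfNum, "", width = 8), collapse = ""),
            con, eos = NULL, useBytes = TRUE)
  writeChar(paste0(vapply(physMax, edfNum, "", width = 8), collapse = ""),
            con, eos = NULL, useBytes = TRUE)
  field(rep(-digMax, ns), 8)
  field(rep(digMax, ns), 8)
  field(rep("", ns), 80)
  field(round(fs), 8)
  field(rep("", ns), 32)

  ## interleave records: for each 1-s record, each signal's fs samples
  perRec <- round(fs)
  blocks <- lapply(seq_len(ns), function(i)
    matrix(dig[[i]], nrow = perRec[i], ncol = nRec))
  inter <- do.call(rbind, blocks)   # (sum fs) x nRec, record-major on cols
  writeBin(as.integer(inter), con, size = 2L, endian = "little")
  invisible(path)
}

readEdfHeader <- function(con) {
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  num <- function(x) as.numeric(trimws(x))
  h <- list(version = trimws(rd(8)), patient = rd(80), recording = rd(80),
            date = rd(8), time = rd(8), headerBytes = num(rd(8)),
            reserved = trimws(rd(44)), nRecords = num(rd(8)),
            recordDuration = num(rd(8)), ns = as.integer(num(rd(4))))
  ns <- h$ns
  fld <- function(width) {
    raw <- rd(width * ns)
    trimws(substring(raw, (seq_len(ns) - 1L) * width + 1L,
                     seq_len(ns) * width))
  }
  h$label <- fld(16); fld(80)
  h$unit <- fld(8)
  h$physMin <- as.numeric(fld(8)); h$physMax <- as.numeric(fld(8))
  h$digMin <- as.numeric(fld(8)); h$digMax <- as.numeric(fld(8))
  fld(80)
  h$samplesPerRecord <- as.integer(fld(8)); fld(32)
  h
}

#' Read an EDF/EDF+ file
#'
#' Low-level reader returning all stored signals in physical units plus any
#' EDF+ annotations. Fails closed: a truncated file raises an error and no
#' partial result is returned.
#'
#' @param path an EDF/EDF+ file.
#' @return List with `header`, `signals` (named list of numeric vectors),
#'   `fs` (named, Hz), `units`, `startTime` and `annotations` (data.frame
#'   with onset, duration, annotation; zero rows if none).
#' @export
readEdf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readEdfHeader(con)
  if (is.na(h$ns) || h$ns < 1L) stop("corrupt EDF header: ", path)
  recBytes <- sum(h$samplesPerRecord) * 2L
  expect <- h$headerBytes + h$nRecords * recBytes
  if (file.size(path) < expect)
    stop("truncated EDF file (", file.size(path), " bytes, expected ",
         expect, "): ", path)
  rawAll <- readBin(con, "raw", n = h$nRecords * recBytes)
  rawMat <- matrix(rawAll, nrow = recBytes)
  offsets <- c(0L, cumsum(h$samplesPerRecord * 2L))

  signals <- list(); fs <- numeric(); units <- character()
  annotations <- data.frame(onset = numeric(), duration = numeric(),
                            annotation = character())
  for (i in seq_len(h$ns)) {
    rows <- (offsets[i] + 1L):offsets[i + 1L]
    bytes <- as.vector(rawMat[rows, , drop = FALSE])
    if (h$label[i] == "EDF Annotations") {
      annotations <- rbind(annotations, parseTals(bytes))
    } else {
      dig <- readBin(bytes, "integer", n = length(bytes) / 2L, size = 2L,
                     signed = TRUE, endian = "little")
      phys <- h$physMin[i] + (dig - h$digMin[i]) *
        (h$physMax[i] - h$physMin[i]) / (h$digMax[i] - h$digMin[i])
      signals[[h$label[i]]] <- phys
      fs[[h$label[i]]] <- h$samplesPerRecord[i] / h$recordDuration
      units[[h$label[i]]] <- h$unit[i]
    }
  }
  dt <- strsplit(h$date, ".", fixed = TRUE)[[1]]
  tm <- strsplit(h$time, ".", fixed = TRUE)[[1]]
  startTime <- tryCatch(
    as.POSIXct(sprintf("%04d-%02d-%02d %s:%s:%s",
                       2000L + as.integer(dt[3]) %% 100, as.integer(dt[2]),
                       as.integer(dt[1]), tm[1], tm[2], tm[3]), tz = "UTC"),
    error = function(e) as.POSIXct("2000-01-01", tz = "UTC"))
  list(header = h, signals = signals, fs = fs, units = units,
       startTime = startTime, annotations = annotations)
}

## Parse EDF+ time-stamped annotation lists from one annotation signal.
parseTals <- function(bytes) {
  ## TALs are NUL-terminated; rawToChar stops at embedded NULs, so split the
  ## raw stream first
  nul <- bytes == as.raw(0)
  grp <- cumsum(c(TRUE, nul[-length(nul)]))
  pieces <- split(bytes, grp)
  tals <- vapply(pieces, function(b) rawToChar(b[b != as.raw(0)]),
                 character(1))
  out <- list()
  for (tal in tals) {
    if (!nzchar(tal)) next
    fields <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (!length(fields)) next
    head <- strsplit(fields[1], "\x15", fixed = TRUE)[[1]]
    onset <- as.numeric(head[1])
    duration <- if (length(head) > 1L) as.numeric(head[2]) else NA_real_
    anns <- fields[-1]
    anns <- anns[nzchar(anns)]
    for (a in anns)
      out[[length(out) + 1L]] <- data.frame(onset = onset,
                                            duration = duration,
                                            annotation = a)
  }
  if (!length(out))
    return(data.frame(onset = numeric(), duration = numeric(),
                      annotation = character()))
  do.call(rbind, out)
}

#' Write a hypnogram as an EDF+ annotation file
#'
#' One time-stamped annotation list (TAL) per stage segment, labelled with
#' the sleep-edfx spellings (`"Sleep stage W"`, `"Sleep stage 1"`, ...,
#' `"Movement time"`), in an annotation-only EDF+ container.
#'
#' @param hyp a [Hypnogram-class].
#' @param path output file path.
#' @param startTime recording start time written to the header.
#' @return `path`, invisibly.
#' @export
writeHypnogramEdf <- function(hyp, path,
                              startTime = as.POSIXct("2000-01-01",
                                                     tz = "UTC")) {
  seg <- segments(hyp)
  spell <- c(W = "Sleep stage W", `1` = "Sleep stage 1",
             `2` = "Sleep stage 2", `3` = "Sleep stage 3",
             `4` = "Sleep stage 4", R = "Sleep stage R",
             M = "Movement time", `?` = "Sleep stage ?")
  num <- function(x) sub("\\.?0+$", "", sprintf("%.3f", x))
  ## NUL-terminated TALs, built as raw since R strings cannot hold NUL
  tals <- lapply(seq_len(nrow(seg)), function(i) {
    c(charToRaw(paste0("+", num(seg$onset[i]), "\x14\x14")), raw(1),
      charToRaw(paste0("+", num(seg$onset[i]), "\x15",
                       num(seg$duration[i]), "\x14",
                       spell[[seg$label[i]]], "\x14")), raw(1))
  })
  recBytes <- max(vapply(tals, length, integer(1)))
  recBytes <- recBytes + recBytes %% 2L          # even: 2-byte "samples"
  nRec <- length(tals)

  st <- as.POSIXlt(startTime)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8), padField("X X X X", 80),
    padField("Startdate X X X X", 80),
    padField(sprintf("%02d.%02d.%02d", st$mday, st$mon + 1L,
                     st$year %% 100), 8),
    padField(sprintf("%02d.%02d.%02d", st$hour, st$min,
                     floor(st$sec)), 8),
    padField(EDF_HEADER_BYTES * 2L, 8),
    padField("EDF+C", 44), padField(nRec, 8), padField(0, 8),
    padField(1, 4),
    padField("EDF Annotations", 16), padField("", 80), padField("", 8),
    padField(-1, 8), padField(1, 8), padField(-32768, 8),
    padField(32767, 8), padField("", 80), padField(recBytes %/% 2L, 8),
    padField("", 32))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  for (b in tals)
    writeBin(c(b, raw(recBytes - length(b))), con)
  invisible(path)
}
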