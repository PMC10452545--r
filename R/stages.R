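## Stage-label configurations: collapsing raw Rechtschaffen--Kales labels
## into the five classification tasks.

#' Stage classification configurations
#'
#' Builds the raw-label to class mapping for one of the five tasks:
#' \describe{
#'   \item{five}{W, N1, N2, N3/N4, R}
#'   \item{four}{W, Light (N1+N2), Deep (N3+N4), R}
#'   \item{three}{W, Non-REM, REM}
#'   \item{two_rem}{Non-REM vs REM (wake dropped)}
#'   \item{two_sleep}{Awake vs Asleep}
#' }
#' Movement time (`M`) and not-scored (`?`) epochs are always dropped.
#'
#' @param name one of `"five"`, `"four"`, `"three"`, `"two_rem"`,
#'   `"two_sleep"`.
#' @return A list with `name`, `mapping` (named character over all eight raw
#'   labels, value `"DROP"` for excluded labels) and `classes` (class levels
#'   in report order).
#' @examples
#' stageConfig("five")$mapping
#' @export
stageConfig <- function(name = c("five", "four", "three", "two_rem",
                                 "two_sleep")) {
  name <- match.arg(name)
  mapping <- switch(name,
    five = c(W = "W", `1` = "N1", `2` = "N2", `3` = "N3/N4", `4` = "N3/N4",
             R = "R"),
    four = c(W = "W", `1` = "Light", `2` = "Light", `3` = "Deep",
             `4` = "Deep", R = "R"),
    three = c(W = "W", `1` = "Non-REM", `2` = "Non-REM", `3` = "Non-REM",
              `4` = "Non-REM", R = "REM"),
    two_rem = c(W = "DROP", `1` = "Non-REM", `2` = "Non-REM",
                `3` = "Non-REM", `4` = "Non-REM", R = "REM"),
    two_sleep = c(W = "Awake", `1` = "Asleep", `2` = "Asleep",
                  `3` = "Asleep", `4` = "Asleep", R = "Asleep"))
  mapping <- c(mapping, M = "DROP", `?` = "DROP")
  classes <- unique(unname(mapping[mapping != "DROP"]))
  list(name = name, mapping = mapping, classes = classes)
}

#' Map hypnogram segments into a stage configuration
#'
#' Applies the configuration's raw-label mapping; segments mapped to `DROP`
#' (always `M` and `?`, plus wake for the REM-vs-NREM task) are removed.
#'
#' @param hyp a [Hypnogram-class].
#' @param config a configuration from [stageConfig()].
#' @return `data.frame` with columns `onset`, `duration`, `class` and `raw`
#'   (the retained raw label), time-ordered.
#' @examples
#' hyp <- hypnogram(c(0, 30, 60), c(30, 30, 30), c("3", "M", "R"))
#' mapStages(hyp, stageConfig("five"))
#' @export
mapStages <- function(hyp, config) {
  if (!all(c("mapping", "classes") %in% names(config)))
    stop("invalid stage configuration")
  seg <- segments(hyp)
  cls <- config$mapping[seg$label]
  if (anyNA(cls))
    stop("stage configuration does not cover label(s): ",
         paste(sQuote(unique(seg$label[is.na(cls)])), collapse = ", "))
  keep <- cls != "DROP"
  data.frame(onset = seg$onset[keep], duration = seg$duration[keep],
             class = unname(cls[keep]), raw = seg$label[keep],
             stringsAsFactors = FALSE)
}

#' Re-label a feature table under another stage configuration
#'
#' Features are unchanged; the per-epoch class labels are recomputed from
#' the stored raw stage labels, so one extraction pass serves all five
#' classification tasks. Epochs whose raw label the configuration drops are
#' removed.
#'
#' @param table a [SleepFeatureTable-class] with raw labels.
#' @param config a configuration from [stageConfig()].
#' @return A [SleepFeatureTable-class] with remapped labels.
#' @export
applyStageConfig <- function(table, config) {
  raw <- rawLabels(table)
  if (anyNA(raw))
    stop("feature table carries no raw stage labels; rebuild it from an ",
         "EpochSet")
  cls <- config$mapping[raw]
  if (anyNA(cls))
    stop("stage configuration does not cover label(s): ",
         paste(sQuote(unique(raw[is.na(cls)])), collapse = ", "))
  keep <- which(cls != "DROP")
  sleepFeatureTable(featureMatrix(table)[keep, , drop = FALSE],
                    labels = factor(unname(cls[keep]),
                                    levels = config$classes),
                    rawLabels = raw[keep])
}
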