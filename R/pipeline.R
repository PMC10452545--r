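## End-to-end orchestration: read/simulate -> filter -> epoch -> map stages
## -> features -> split -> (SMOTE) -> CV -> fit -> evaluate.

#' Default pipeline configuration
#'
#' @param stages stage configuration name (see [stageConfig()]).
#' @param seed master integer seed; all stage seeds derive from it.
#' @return Nested configuration list accepted by [runPipeline()].
#' @export
defaultPipelineConfig <- function(stages = "five", seed = 1L) {
  list(
    simulate = TRUE, hours = 9, psg = NULL, hypnogram = NULL,
    stages = stages, seed = as.integer(seed),
    filter = list(lFreq = 0.3, hFreq = 40),
    epoch = list(lengthS = 30),
    measures = "all",
    featureParams = defaultFeatureParams(),
    smote = list(enabled = TRUE, kNeighbors = 5L, beforeCv = FALSE),
    split = list(trainFraction = 0.8),
    cv = list(enabled = FALSE, folds = 15L),
    learner = list(name = "xgboost", hyperparameters = list()))
}

#' Run the full sleep-staging pipeline
#'
#' Reads (or simulates) a PSG recording and hypnogram, band-pass filters the
#' whole recording, extracts labelled 30-s epochs under the chosen stage
#' configuration, builds the feature table, makes a stratified 80/20 split,
#' SMOTE-balances the training part, optionally cross-validates on the
#' training part, then fits the learner and evaluates it on the untouched,
#' imbalanced test set. All seeds and the SMOTE placement are recorded in
#' the report's `meta`.
#'
#' @param config configuration list, see [defaultPipelineConfig()]. Partial
#'   lists are merged over the defaults.
#' @param featureTable optional precomputed [SleepFeatureTable-class] with
#'   raw labels; when given, the simulation/reading/filtering/feature steps
#'   are skipped and only the stage mapping, split, SMOTE, CV and evaluation
#'   run (one extraction pass can then serve all five stage tasks).
#' @return An [EvaluationReport-class].
#' @export
runPipeline <- function(config = list(), featureTable = NULL) {
  cfg <- utils::modifyList(defaultPipelineConfig(), config)
  seed <- as.integer(cfg$seed)
  scfg <- stageConfig(cfg$stages)

  if (is.null(featureTable)) {
    if (isTRUE(cfg$simulate)) {
      sim <- simulatePsg(hours = cfg$hours, seed = seed)
      rec <- sim$recording; hyp <- sim$hypnogram
    } else {
      if (is.null(cfg$psg) || is.null(cfg$hypnogram))
        stop("config must give 'psg' and 'hypnogram' paths or simulate=TRUE")
      rec <- readRecording(cfg$psg)
      hyp <- readHypnogram(cfg$hypnogram)
    }
    rec <- filterRecording(rec, lFreq = cfg$filter$lFreq,
                           hFreq = cfg$filter$hFreq)
    eps <- extractEpochs(rec, mapStages(hyp, scfg),
                         epochLen = cfg$epoch$lengthS,
                         classes = scfg$classes)
    featureTable <- buildFeatureTable(eps, measures = cfg$measures,
                                      params = cfg$featureParams)
  } else {
    featureTable <- applyStageConfig(featureTable, scfg)
    if (!identical(cfg$measures, "all"))
      featureTable <- selectMeasures(featureTable, cfg$measures)
  }

  parts <- splitTrainTest(featureTable,
                          trainFraction = cfg$split$trainFraction,
                          seed = seed + 1L)
  cv <- data.frame()
  if (isTRUE(cfg$cv$enabled)) {
    cvRes <- crossValidate(parts$train,
                           spec = learnerSpec(cfg$learner$name,
                                              cfg$learner$hyperparameters,
                                              seed = seed + 2L),
                           folds = cfg$cv$folds,
                           smote = isTRUE(cfg$smote$enabled),
                           kNeighbors = cfg$smote$kNeighbors,
                           smoteBeforeCv = isTRUE(cfg$smote$beforeCv),
                           seed = seed + 3L)
    cv <- cvRes$perFold
  }
  trainTab <- parts$train
  if (isTRUE(cfg$smote$enabled))
    trainTab <- smoteOversample(trainTab, kNeighbors = cfg$smote$kNeighbors,
                                seed = seed + 4L)
  model <- fitLearner(trainTab, learnerSpec(cfg$learner$name,
                                            cfg$learner$hyperparameters,
                                            seed = seed + 2L))
  evaluateModel(model, parts$test, cv = cv,
                meta = list(stages = cfg$stages, measures = cfg$measures,
                            learner = cfg$learner$name, seed = seed,
                            smote = cfg$smote, split = cfg$split,
                            cvFolds = if (isTRUE(cfg$cv$enabled))
                              as.integer(cfg$cv$folds) else 0L))
}

#' Subset a feature table to selected measures
#'
#' Keeps the columns whose `"{channel}::{measure}"` name matches one of the
#' requested measures.
#'
#' @param table a [SleepFeatureTable-class].
#' @param measures character vector of measure names (see
#'   [buildFeatureTable()]); moments match their four column suffixes.
#' @return A [SleepFeatureTable-class] with the matching columns only.
#' @export
selectMeasures <- function(table, measures) {
  if (identical(measures, "all")) return(table)
  bad <- setdiff(measures, FEATURE_MEASURES)
  if (length(bad))
    stop("unknown measure(s): ", paste(sQuote(bad), collapse = ", "))
  parts <- strsplit(featureNames(table), "::", fixed = TRUE)
  m <- vapply(parts, `[`, "", 2L)
  m[m %in% c("mean", "sd", "skewness", "kurtosis")] <- "moments"
  keep <- m %in% measures
  if (!any(keep)) stop("no columns match measures: ",
                       paste(measures, collapse = ", "))
  sleepFeatureTable(featureMatrix(table)[, keep, drop = FALSE],
                    labels = epochLabels(table),
                    rawLabels = rawLabels(table))
}
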