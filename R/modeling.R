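## Train/test splitting, stratified cross-validation and the evaluation
## metric set (recall, precision, accuracy, F1, macro one-vs-rest AUC).

#' Stratified train/test split
#'
#' Splits epochs into disjoint train and test tables, stratified by class
#' label: each class contributes `1 - trainFraction` of its rows (rounded,
#' at least one) to the test set. The test set is never oversampled, so it
#' keeps the natural class imbalance. Deterministic given `seed`.
#'
#' @param table a [SleepFeatureTable-class] with at least 2 rows per class.
#' @param trainFraction fraction of rows used for training (default 0.8).
#' @param seed integer RNG seed.
#' @return List with elements `train` and `test`.
#' @export
splitTrainTest <- function(table, trainFraction = 0.8, seed = 1L) {
  stopifnot(trainFraction > 0, trainFraction < 1)
  y <- droplevels(as.factor(epochLabels(table)))
  counts <- base::table(y)
  if (any(counts < 2L))
    stop("class(es) with fewer than 2 rows cannot be split: ",
         paste(sQuote(names(counts)[counts < 2L]), collapse = ", "))
  testIdx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      nTest <- max(1L, round((1 - trainFraction) * length(idx)))
      sample(idx, nTest)
    }))
  })
  testIdx <- sort(testIdx)
  list(train = table[, -testIdx], test = table[, testIdx])
}

## Per-class one-vs-rest counts and derived metrics from a confusion matrix.
#' Metrics from a confusion matrix
#'
#' Computes, for each class treated one-vs-rest, the true/false
#' positive/negative counts and recall (TP / (TP + FN)), precision
#' (TP / (TP + FP)), F1 (harmonic mean of the two) and support, plus the
#' overall accuracy (sum of the diagonal over the total, identical to
#' micro-averaged recall) and macro averages.
#'
#' @param cm square class-by-class count matrix; rows are true classes,
#'   columns predictions.
#' @return List with `perClass` (data.frame), `accuracy`, `macroRecall`,
#'   `macroPrecision` (fractions).
#' @examples
#' confusionMetrics(matrix(c(8, 1, 2, 9), 2))$accuracy  # 0.85
#' @export
confusionMetrics <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm))
  classes <- rownames(cm)
  if (is.null(classes)) classes <- paste0("class", seq_len(nrow(cm)))
  total <- sum(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  f1 <- ifelse(!is.na(recall) & !is.na(precision) & (recall + precision) > 0,
               2 * precision * recall / (precision + recall), NA_real_)
  perClass <- data.frame(class = classes, tp = tp, fp = fp, fn = fn, tn = tn,
                         recall = recall, precision = precision, f1 = f1,
                         support = rowSums(cm), row.names = NULL,
                         stringsAsFactors = FALSE)
  list(perClass = perClass, accuracy = sum(tp) / total,
       macroRecall = mean(recall, na.rm = TRUE),
       macroPrecision = mean(precision, na.rm = TRUE))
}

## Macro one-vs-rest AUC from class-probability scores; classes absent from
## the truth vector are skipped.
macroAuc <- function(y, prob) {
  y <- as.character(y)
  aucs <- vapply(colnames(prob), function(cl) {
    pos <- y == cl
    if (!any(pos) || all(pos)) return(NA_real_)
    as.numeric(pROC::auc(response = factor(pos, levels = c(FALSE, TRUE)),
                         predictor = prob[, cl], quiet = TRUE,
                         direction = "<"))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Evaluate a fitted model on held-out data
#'
#' Predicts class probabilities on the test table, takes the argmax class,
#' and reports the confusion matrix, per-class precision/recall/F1/support,
#' overall accuracy and macro one-vs-rest AUC.
#'
#' @param model a fitted model from [fitLearner()].
#' @param table a test [SleepFeatureTable-class] with the training schema.
#' @param cv optional data.frame of per-fold CV metrics to embed in the
#'   report.
#' @param meta optional list of run parameters to record.
#' @return An [EvaluationReport-class].
#' @export
evaluateModel <- function(model, table, cv = NULL, meta = list()) {
  prob <- predictProb(model, table)
  pred <- factor(model$classes[max.col(prob, ties.method = "first")],
                 levels = model$classes)
  truth <- factor(as.character(epochLabels(table)), levels = model$classes)
  cm <- base::table(truth = truth, predicted = pred)
  cm <- matrix(as.integer(cm), nrow = nrow(cm), dimnames = dimnames(cm))
  met <- confusionMetrics(cm)
  if (is.null(cv)) cv <- data.frame()
  new("EvaluationReport", confusion = cm,
      perClass = met$perClass[, c("class", "precision", "recall", "f1",
                                  "support")],
      accuracy = met$accuracy,
      macroAUC = macroAuc(truth, prob),
      cv = cv, meta = meta)
}

#' Stratified k-fold cross-validation with fold-internal SMOTE
#'
#' Splits the training table into `folds` stratified folds; for each fold,
#' the remaining folds are (optionally) SMOTE-balanced, the learner is
#' fitted and evaluated on the untouched held-out fold. Per-fold accuracy,
#' macro recall, macro precision and macro AUC are averaged arithmetically.
#' A degenerate fold whose training part lost a class entirely is skipped
#' with a warning and recorded.
#'
#' @param table training [SleepFeatureTable-class].
#' @param spec a [learnerSpec()].
#' @param folds number of folds (default 15).
#' @param smote logical, rebalance each fold's training part with SMOTE
#'   (default TRUE). Set `smoteBeforeCv = TRUE` to reproduce the
#'   alternative placement where the whole table is oversampled once before
#'   folding (leaks synthetic points into validation folds; off by
#'   default).
#' @param kNeighbors SMOTE neighbourhood size.
#' @param smoteBeforeCv see `smote`.
#' @param seed integer RNG seed for fold assignment and SMOTE.
#' @return List with `perFold` (data.frame of per-fold metrics) and
#'   `means` (named vector: accuracy, recall, precision, auc).
#' @export
crossValidate <- function(table, spec = learnerSpec(), folds = 15L,
                          smote = TRUE, kNeighbors = 5L,
                          smoteBeforeCv = FALSE, seed = 1L) {
  stopifnot(folds >= 2L)
  seed <- as.integer(seed)
  if (smote && smoteBeforeCv)
    table <- smoteOversample(table, kNeighbors = kNeighbors, seed = seed)
  y <- droplevels(as.factor(epochLabels(table)))
  if (min(base::table(y)) < folds)
    stop("smallest class (", min(base::table(y)),
         " rows) has fewer rows than folds (", folds, ")")
  foldId <- withr::with_seed(seed, {
    id <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    id
  })
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    trainTab <- table[, foldId != f]
    testTab <- table[, foldId == f]
    if (nlevels(droplevels(as.factor(epochLabels(trainTab)))) < nlevels(y)) {
      warning("fold ", f, " lost a class in training; skipped")
      rows[[f]] <- data.frame(fold = f, accuracy = NA_real_,
                              recall = NA_real_, precision = NA_real_,
                              auc = NA_real_, skipped = TRUE)
      next
    }
    if (smote && !smoteBeforeCv)
      trainTab <- smoteOversample(trainTab, kNeighbors = kNeighbors,
                                  seed = seed + f)
    model <- fitLearner(trainTab, spec)
    prob <- predictProb(model, testTab)
    pred <- factor(model$classes[max.col(prob, ties.method = "first")],
                   levels = model$classes)
    truth <- factor(as.character(epochLabels(testTab)),
                    levels = model$classes)
    met <- confusionMetrics(base::table(truth, pred))
    rows[[f]] <- data.frame(fold = f, accuracy = met$accuracy,
                            recall = met$macroRecall,
                            precision = met$macroPrecision,
                            auc = macroAuc(truth, prob), skipped = FALSE)
  }
  perFold <- do.call(rbind, rows)
  means <- colMeans(perFold[!perFold$skipped,
                            c("accuracy", "recall", "precision", "auc")],
                    na.rm = TRUE)
  list(perFold = perFold, means = means)
}
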