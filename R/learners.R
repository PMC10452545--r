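## Pluggable multi-class learners behind a fit / predict-probabilities
## contract. Tree ensembles are never re-implemented here; the package
## delegates to xgboost, randomForest and ranger and only standardises the
## interface and determinism (single thread, fixed seeds).

#' Specify a learner
#'
#' @param name one of `"xgboost"`, `"random_forest"`, `"extra_trees"`.
#'   `"lightgbm"` is recognised but has no installed R backend and raises
#'   an informative error when fitted.
#' @param hyperparameters named list overriding the backend defaults.
#' @param seed integer seed used at fit time.
#' @return A learner specification list.
#' @export
learnerSpec <- function(name = c("xgboost", "random_forest", "extra_trees",
                                 "lightgbm"),
                        hyperparameters = list(), seed = 1L) {
  name <- match.arg(name)
  list(name = name, hyperparameters = hyperparameters,
       seed = as.integer(seed))
}

#' Fit a classifier on a feature table
#'
#' @param table a training [SleepFeatureTable-class].
#' @param spec a [learnerSpec()].
#' @return Fitted model object with class `"somnostageModel"`, usable with
#'   [predictProb()] and [evaluateModel()].
#' @export
fitLearner <- function(table, spec = learnerSpec()) {
  X <- featureMatrix(table)
  y <- droplevels(as.factor(epochLabels(table)))
  classes <- levels(y)
  hp <- spec$hyperparameters
  fit <- switch(spec$name,
    xgboost = {
      pars <- utils::modifyList(
        list(objective = "multi:softprob", num_class = length(classes),
             max_depth = 4, eta = 0.3, nthread = 1,
             eval_metric = "mlogloss"),
        hp[setdiff(names(hp), "nrounds")])
      nrounds <- if (!is.null(hp$nrounds)) hp$nrounds else 100
      set.seed(spec$seed)
      xgboost::xgb.train(
        params = pars,
        data = xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L),
        nrounds = nrounds, verbose = 0)
    },
    random_forest = {
      set.seed(spec$seed)
      do.call(randomForest::randomForest,
              c(list(x = X, y = y),
                utils::modifyList(list(ntree = 300), hp)))
    },
    extra_trees = {
      do.call(ranger::ranger,
              c(list(x = X, y = y, probability = TRUE,
                     seed = spec$seed, num.threads = 1L),
                utils::modifyList(list(num.trees = 300,
                                       splitrule = "extratrees",
                                       num.random.splits = 1L), hp)))
    },
    lightgbm = stop("learner 'lightgbm' has no installed R backend; ",
                    "use 'xgboost', 'random_forest' or 'extra_trees'"))
  structure(list(backend = spec$name, fit = fit, classes = classes,
                 featureNames = colnames(X), spec = spec),
            class = "somnostageModel")
}

#' Class-probability predictions
#'
#' @param model a fitted model from [fitLearner()].
#' @param table a [SleepFeatureTable-class] whose features match the
#'   training schema.
#' @return Numeric matrix, one row per epoch, one column per class.
#' @export
predictProb <- function(model, table) {
  stopifnot(inherits(model, "somnostageModel"))
  X <- featureMatrix(table)
  missing <- setdiff(model$featureNames, colnames(X))
  if (length(missing))
    stop("test table schema mismatch; missing columns: ",
         paste(utils::head(missing, 10), collapse = ", "))
  X <- X[, model$featureNames, drop = FALSE]
  prob <- switch(model$backend,
    xgboost = {
      p <- predict(model$fit, xgboost::xgb.DMatrix(X))
      if (is.matrix(p)) p else matrix(p, ncol = length(model$classes),
                                      byrow = TRUE)
    },
    random_forest = unname(predict(model$fit, X, type = "prob")),
    extra_trees = {
      p <- predict(model$fit, data = X, num.threads = 1L)$predictions
      p[, model$classes, drop = FALSE]
    })
  colnames(prob) <- model$classes
  prob
}
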