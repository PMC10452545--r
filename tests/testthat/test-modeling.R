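# Splitting, cross-validation, metric identities and learner backends.

test_that("confusion-matrix metrics reproduce the defining count ratios", {
  cm <- matrix(c(8, 2, 1, 9), nrow = 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  met <- confusionMetrics(cm)
  expect_equal(met$accuracy, 0.85)
  expect_equal(met$perClass$recall[1], 8 / 10)
  expect_equal(met$perClass$precision[1], 8 / 9)
  expect_equal(met$perClass$f1[1],
               2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))
  expect_equal(met$perClass$support, c(10, 10))
})

test_that("micro-averaged recall equals accuracy on random confusion matrices", {
  set.seed(11)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    cm <- matrix(rpois(k * k, 8) + 1, k)
    met <- confusionMetrics(cm)
    microRecall <- sum(diag(cm)) / sum(cm)   # pooled TP over pooled TP+FN
    expect_equal(met$accuracy, microRecall)
    # macro recall equals accuracy iff class supports are equal
    cmEq <- cm
    cmEq <- t(apply(cm, 1, function(r) round(r * 100 / sum(r))))
    diag(cmEq) <- diag(cmEq) + (100 - rowSums(cmEq))
    metEq <- confusionMetrics(cmEq)
    expect_equal(metEq$macroRecall, metEq$accuracy)
  }
})

test_that("a degenerate one-class predictor yields 100%/0% recalls", {
  cm <- matrix(c(10, 0, 5, 0), 2, byrow = TRUE,
               dimnames = list(c("x", "y"), c("x", "y")))
  met <- confusionMetrics(cm)
  expect_equal(met$perClass$recall, c(1, 0))
})

test_that("the stratified 80/20 split has per-class test counts within one row of 20%", {
  ft <- toyFeatureTable(n = 100, classes = c("A", "B"))
  sp <- splitTrainTest(ft, seed = 4)
  trainY <- table(epochLabels(sp$train))
  testY <- table(epochLabels(sp$test))
  expect_equal(unname(trainY), c(40L, 40L), ignore_attr = TRUE)
  expect_equal(unname(testY), c(10L, 10L), ignore_attr = TRUE)
  ft5 <- toyFeatureTable(n = 137, classes = paste0("c", 1:5))
  sp5 <- splitTrainTest(ft5, seed = 5)
  y <- table(epochLabels(ft5))
  yt <- table(epochLabels(sp5$test))
  expect_true(all(abs(yt - 0.2 * y) <= 1))
  expect_equal(nEpochs(sp5$train) + nEpochs(sp5$test), 137L)
})

test_that("splits are deterministic and disjoint", {
  ft <- toyFeatureTable(n = 80)
  s1 <- splitTrainTest(ft, seed = 9)
  s2 <- splitTrainTest(ft, seed = 9)
  expect_identical(colnames(s1$test), colnames(s2$test))
  expect_length(intersect(colnames(s1$test), colnames(s1$train)), 0)
  expect_error(splitTrainTest(sleepFeatureTable(matrix(1:4, 2,
                              dimnames = list(NULL, c("a", "b"))),
                              labels = c("A", "B"))), "fewer than 2")
})

test_that("cross-validation is perfect on separable classes and honours the fold count", {
  # zero within-class spread: no held-out point can fall inside the margin
  ft <- toyFeatureTable(n = 90, classes = c("A", "B"), sdNoise = 0)
  res <- crossValidate(ft, learnerSpec("xgboost",
                                       list(nrounds = 20, max_depth = 2)),
                       folds = 15, smote = FALSE, seed = 2)
  expect_equal(nrow(res$perFold), 15L)
  expect_equal(unname(res$means["accuracy"]), 1)
  expect_gt(res$means["auc"], 0.99)
})

test_that("label-shuffled balanced data scores at chance level", {
  accs <- numeric(5)
  for (r in 1:5) {
    ft <- withr::with_seed(100 + r, {
      X <- matrix(rnorm(600 * 6), ncol = 6,
                  dimnames = list(NULL, paste0("f", 1:6)))
      sleepFeatureTable(X, labels = rep(paste0("c", 1:5), each = 120))
    })
    res <- crossValidate(ft, learnerSpec("xgboost",
                                         list(nrounds = 15, max_depth = 2)),
                         folds = 5, smote = FALSE, seed = r)
    accs[r] <- res$means["accuracy"]
  }
  expect_equal(mean(accs), 0.2, tolerance = 0.15)  # 20% +/- 3 points
})

test_that("fold-internal SMOTE balances only the training side of each fold", {
  ft <- imbalancedTable <- withr::with_seed(13, {
    X <- rbind(matrix(rnorm(90 * 3, 0), ncol = 3),
               matrix(rnorm(30 * 3, 3), ncol = 3))
    colnames(X) <- paste0("f", 1:3)
    sleepFeatureTable(X, labels = c(rep("A", 90), rep("B", 30)))
  })
  res <- crossValidate(ft, learnerSpec("xgboost", list(nrounds = 10)),
                       folds = 5, smote = TRUE, seed = 3)
  expect_equal(nrow(res$perFold), 5L)
  expect_false(any(res$perFold$skipped))
  expect_gt(res$means["accuracy"], 0.8)
})

test_that("all installed learner backends fit and emit proper probabilities", {
  ft <- toyFeatureTable(n = 120, classes = c("A", "B", "C"), sdNoise = 0.2)
  sp <- splitTrainTest(ft, seed = 1)
  for (nm in c("xgboost", "random_forest", "extra_trees")) {
    model <- fitLearner(sp$train, learnerSpec(nm, seed = 5))
    prob <- predictProb(model, sp$test)
    expect_identical(colnames(prob), c("A", "B", "C"))
    expect_equal(unname(rowSums(prob)), rep(1, nrow(prob)),
                 tolerance = 1e-6)
    rep <- evaluateModel(model, sp$test)
    expect_gte(overallAccuracy(rep), 0.8)
    expect_equal(sum(confusionMatrix(rep)), nEpochs(sp$test))
  }
  expect_error(fitLearner(sp$train, learnerSpec("lightgbm")),
               "no installed R backend")
})

test_that("evaluation rejects mismatched schemas and fills the report", {
  ft <- toyFeatureTable(n = 60)
  sp <- splitTrainTest(ft, seed = 2)
  model <- fitLearner(sp$train, learnerSpec("xgboost", list(nrounds = 10)))
  other <- sleepFeatureTable(matrix(rnorm(20), 10, 2,
                                    dimnames = list(NULL, c("g1", "g2"))),
                             labels = rep(c("A", "B"), 5))
  expect_error(predictProb(model, other), "missing columns")
  rep <- evaluateModel(model, sp$test)
  expect_s4_class(rep, "EvaluationReport")
  pc <- perClassMetrics(rep)
  expect_identical(pc$class, c("A", "B"))
  expect_equal(sum(pc$support), nEpochs(sp$test))
  expect_equal(unname(rowSums(confusionMatrix(rep))), pc$support)
})
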