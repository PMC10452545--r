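## Synthetic Minority Oversampling Technique (classic interpolation SMOTE),
## applied to training data only -- never to a held-out fold or test set.

#' Oversample minority classes with SMOTE
#'
#' Every class is brought up to the majority-class count by synthesizing
#' points on segments between a minority sample and one of its `kNeighbors`
#' nearest same-class neighbours (Euclidean distance in feature space):
#' each synthetic row is \eqn{x + u (x_{nn} - x)} with \eqn{u \sim U(0,1)}.
#' Original rows are preserved unchanged and synthetic rows always carry
#' their parent class's label. Deterministic given `seed`.
#'
#' @param table a [SleepFeatureTable-class] with at least two classes.
#' @param kNeighbors number of nearest neighbours (default 5); every
#'   minority class must have more than `kNeighbors` members.
#' @param seed integer RNG seed.
#' @return A [SleepFeatureTable-class] with exactly equal class counts.
#' @export
smoteOversample <- function(table, kNeighbors = 5L, seed = 1L) {
  stopifnot(is(table, "SleepFeatureTable"), kNeighbors >= 1L)
  X <- featureMatrix(table)
  y <- droplevels(as.factor(epochLabels(table)))
  raw <- rawLabels(table)
  counts <- base::table(y)   # arg `table` shadows base::table
  if (length(counts) < 2L) stop("SMOTE needs at least two classes")
  target <- max(counts)
  minority <- names(counts)[counts < target]
  small <- names(counts)[counts <= kNeighbors & counts < target]
  if (length(small))
    stop("class(es) too small for SMOTE with k=", kNeighbors, ": ",
         paste(sQuote(small), collapse = ", "))

  synth <- list(); synthLab <- character(0); synthRaw <- character(0)
  withr::with_seed(as.integer(seed), {
    for (cl in minority) {
      idx <- which(y == cl)
      Xc <- X[idx, , drop = FALSE]
      nC <- nrow(Xc)
      d <- as.matrix(stats::dist(Xc))
      diag(d) <- Inf
      nnIdx <- t(apply(d, 1L, function(r)
        order(r)[seq_len(min(kNeighbors, nC - 1L))]))
      nGen <- target - nC
      base <- sample.int(nC, nGen, replace = TRUE)
      pick <- sample.int(ncol(nnIdx), nGen, replace = TRUE)
      u <- stats::runif(nGen)
      nn <- nnIdx[cbind(base, pick)]
      newX <- Xc[base, , drop = FALSE] +
        u * (Xc[nn, , drop = FALSE] - Xc[base, , drop = FALSE])
      rownames(newX) <- sprintf("synth_%s_%d", gsub("[^A-Za-z0-9]", "", cl),
                                seq_len(nGen))
      synth[[cl]] <- newX
      synthLab <- c(synthLab, rep(cl, nGen))
      synthRaw <- c(synthRaw, rep(NA_character_, nGen))
    }
  })
  if (!length(synth)) return(table)
  allX <- rbind(X, do.call(rbind, synth))
  sleepFeatureTable(allX,
                    labels = factor(c(as.character(y), synthLab),
                                    levels = levels(y)),
                    rawLabels = c(raw, synthRaw))
}
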