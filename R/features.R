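## Per-epoch feature estimators: Welch PSD, SVD entropy, Higuchi fractal
## dimension, permutation entropy, detrended fluctuation analysis and
## statistical moments. These are the measures the classifier learns from;
## each has a brute-force oracle in the test suite.

#' Welch power spectral density
#'
#' Periodogram averaging: the series is cut into overlapping segments of
#' `segmentLen` samples shifted by `shift`, each segment is windowed and its
#' periodogram \eqn{P_k(v) = |X_k(v)|^2 / W} formed with the window energy
#' \eqn{W = \sum_m w(m)^2}; the PSD is the mean periodogram over segments.
#' Output is the one-sided density (scaled by \eqn{2/(f_s W)}, DC and
#' Nyquist bins not doubled) so that the integral of the PSD over frequency
#' equals the signal variance, restricted to `[fmin, fmax]`.
#'
#' @param x numeric series (one epoch of one channel).
#' @param fs sampling rate (Hz).
#' @param segmentLen segment length M in samples (default 256).
#' @param shift segment shift S in samples (default `segmentLen / 2`,
#'   i.e. 50\% overlap).
#' @param window window samples of length `segmentLen` (default Hamming).
#' @param fmin,fmax retained frequency band in Hz (defaults 0.3 and 40,
#'   matching the band-pass).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @examples
#' x <- sin(2 * pi * 10 * seq_len(3000) / 100)
#' p <- welchPsd(x, fs = 100)
#' p$freq[which.max(p$psd)]
#' @export
welchPsd <- function(x, fs, segmentLen = 256L, shift = NULL, window = NULL,
                     fmin = 0.3, fmax = 40) {
  M <- as.integer(segmentLen)
  if (length(x) < M)
    stop("series (", length(x), ") shorter than Welch segment length (",
         M, ")")
  if (is.null(shift)) shift <- M %/% 2L
  S <- as.integer(shift)
  stopifnot(S >= 1L, S <= M)
  if (is.null(window)) window <- hammingWindow(M)
  stopifnot(length(window) == M, all(window >= 0))
  if (!(fmin < fmax && fmax <= fs / 2)) stop("need fmin < fmax <= fs/2")
  K <- (length(x) - M) %/% S + 1L
  starts <- (seq_len(K) - 1L) * S
  segs <- vapply(starts, function(s) x[s + seq_len(M)] * window,
                 numeric(M))
  spec <- Mod(stats::mvfft(segs))^2
  W <- sum(window^2)
  nb <- M %/% 2L + 1L                      # one-sided bins
  psd <- rowMeans(spec[seq_len(nb), , drop = FALSE]) / W
  scale <- rep(2 / fs, nb)
  scale[1L] <- 1 / fs                      # DC not doubled
  if (M %% 2L == 0L) scale[nb] <- 1 / fs   # Nyquist not doubled
  psd <- psd * scale
  freq <- (seq_len(nb) - 1L) * fs / M
  keep <- freq >= fmin & freq <= fmax
  list(freq = freq[keep], psd = psd[keep])
}

## Delay-embedding matrix: rows y(i) = (x_i, x_{i+tau}, ..., x_{i+(d-1)tau}).
delayEmbed <- function(x, order, delay) {
  nr <- length(x) - (order - 1L) * delay
  if (nr < 1L)
    stop("series too short for embedding (order ", order, ", delay ",
         delay, ")")
  vapply(seq_len(order), function(j) x[seq_len(nr) + (j - 1L) * delay],
         numeric(nr))
}

#' Singular value decomposition entropy
#'
#' Shannon entropy (bits) of the L1-normalised singular values of the
#' delay-embedding matrix. Low for regular signals (few dominant modes),
#' approaching `log2(order)` for isotropic noise. A constant series has a
#' rank-one embedding and returns 0 (the `0 log 0 = 0` convention).
#'
#' @param x numeric series.
#' @param order embedding dimension (default 3).
#' @param delay embedding delay in samples (default 1).
#' @return SVD entropy in bits, in `[0, log2(order)]`.
#' @export
svdEntropy <- function(x, order = 3L, delay = 1L) {
  stopifnot(order >= 2L, delay >= 1L)
  Y <- delayEmbed(x, order, delay)
  s <- svd(Y, nu = 0L, nv = 0L)$d
  if (sum(s) <= 0) return(0)
  p <- s / sum(s)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Higuchi fractal dimension
#'
#' Curve-length scaling estimate: for each interval `k = 1..kmax` and start
#' offset `m`, the length of the sub-sampled curve is
#' \deqn{L_m(k) = \frac{N - 1}{\lfloor (N-m)/k \rfloor \, k^2}
#'   \sum_i |x(m + ik) - x(m + (i-1)k)|,}
#' `L(k)` is the mean over the `k` offsets, and the dimension is the
#' least-squares slope of `log L(k)` against `log(1/k)`. Values lie in
#' `[1, 2]`: 1 for smooth curves, 2 for space-filling noise. A constant
#' series (zero curve length) returns 1 by convention.
#'
#' @param x numeric series of length at least `2 * kmax`.
#' @param kmax largest interval (default 10).
#' @return Fractal dimension estimate.
#' @export
higuchiFd <- function(x, kmax = 10L) {
  N <- length(x)
  stopifnot(kmax >= 2L, N >= 2L * kmax)
  L <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      nI <- (N - m) %/% k
      if (nI < 1L) { Lm[m] <- NA_real_; next }
      idx <- m + (0:nI) * k
      Lm[m] <- sum(abs(diff(x[idx]))) * (N - 1) / (nI * k) / k
    }
    L[k] <- mean(Lm, na.rm = TRUE)
  }
  if (all(L == 0)) return(1.0)
  ok <- L > 0
  fit <- stats::lm.fit(cbind(1, log(1 / seq_len(kmax)[ok])),
                       log(L[ok]))
  unname(fit$coefficients[2L])
}

#' Permutation entropy
#'
#' Shannon entropy (bits) of the distribution of ordinal patterns of
#' `order`-length delay vectors. Ties are resolved by order of appearance.
#' A monotone series has a single pattern (entropy 0); continuous white
#' noise approaches the uniform limit `log2(order!)`.
#'
#' @param x numeric series.
#' @param order pattern length D, recommended in 3..7 (default 3).
#' @param delay delay in samples (default 1).
#' @return Permutation entropy in bits, in `[0, log2(factorial(order))]`.
#' @examples
#' permutationEntropy(c(4, 7, 9, 10, 6, 11, 3), order = 3)
#' @export
permutationEntropy <- function(x, order = 3L, delay = 1L) {
  stopifnot(order >= 2L, order <= 7L, delay >= 1L)
  m <- delayEmbed(x, order, delay)
  ## ranks with ties broken by first appearance, vectorised over rows
  r <- matrix(1L, nrow(m), order)
  for (j in seq_len(order))
    for (k in seq_len(order)) {
      if (k == j) next
      r[, j] <- r[, j] + (m[, k] < m[, j]) +
        (k < j) * (m[, k] == m[, j])
    }
  code <- as.vector((r - 1L) %*% order^(seq_len(order) - 1L))
  p <- tabulate(match(code, unique(code)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Detrended fluctuation analysis
#'
#' Scaling exponent of root-mean-square fluctuations: the mean-centred
#' series is integrated, split into non-overlapping windows of `n` samples,
#' a least-squares line is removed per window, and
#' \eqn{F(n) = \sqrt{\frac{1}{N'}\sum_k (y(k) - y_n(k))^2}} is computed over
#' the covered samples. The exponent \eqn{\alpha} is the slope of
#' `log F(n)` versus `log n`: about 0.5 for white noise, about 1.5 for a
#' Brownian path.
#'
#' @param x numeric series.
#' @param scales increasing integer window sizes; default 12 log-spaced
#'   sizes from 8 to `length(x)/4`.
#' @return The scaling exponent alpha.
#' @export
dfa <- function(x, scales = NULL) {
  N <- length(x)
  if (is.null(scales)) {
    scales <- unique(round(exp(seq(log(8), log(N / 4), length.out = 12))))
    scales <- scales[scales <= N %/% 4L]
  }
  scales <- sort(unique(as.integer(scales)))
  stopifnot(min(scales) >= 4L, max(scales) <= N %/% 4L,
            length(scales) >= 2L)
  if (stats::sd(x) == 0)
    stop("DFA is undefined for a constant series (zero fluctuation)")
  y <- cumsum(x - mean(x))
  Fn <- vapply(scales, function(n) {
    nw <- N %/% n
    Ym <- matrix(y[seq_len(n * nw)], nrow = n)
    tc <- seq_len(n) - (n + 1) / 2
    b <- colSums(Ym * tc) / sum(tc^2)
    resid <- Ym - rep(colMeans(Ym), each = n) - outer(tc, b)
    sqrt(mean(resid^2))
  }, numeric(1))
  if (any(Fn <= 0)) stop("DFA is undefined: zero fluctuation at some scale")
  fit <- stats::lm.fit(cbind(1, log(scales)), log(Fn))
  unname(fit$coefficients[2L])
}

#' Statistical moments of an epoch
#'
#' Mean, population standard deviation (`N` in the denominator), skewness
#' with the mixed `(N-1) sigma^3` denominator, and non-excess (Pearson)
#' kurtosis \eqn{\mu_4 / \sigma^4} (3 for a Gaussian; no `-3` correction).
#' For a zero-variance series, skewness and kurtosis are undefined and are
#' imputed to 0 and 3 with a warning so a single flat channel cannot abort
#' a run.
#'
#' @param x numeric series, length at least 2.
#' @return Named numeric vector `mean`, `sd`, `skewness`, `kurtosis`.
#' @examples
#' signalMoments(1:5)   # mean 3, sd sqrt(2), skewness 0, kurtosis 1.7
#' @export
signalMoments <- function(x) {
  N <- length(x)
  stopifnot(N >= 2L)
  mu <- mean(x)
  d <- x - mu
  sigma <- sqrt(sum(d^2) / N)
  if (sigma == 0) {
    warning("zero-variance series: skewness/kurtosis imputed to 0 and 3")
    return(c(mean = mu, sd = 0, skewness = 0, kurtosis = 3))
  }
  c(mean = mu, sd = sigma,
    skewness = sum(d^3) / ((N - 1) * sigma^3),
    kurtosis = (sum(d^4) / N) / sigma^4)
}

#' Default feature-extraction parameters
#'
#' @return Nested list of per-measure parameters (Welch segment length and
#'   band, embedding orders and delays, Higuchi `kmax`, DFA scales).
#' @export
defaultFeatureParams <- function() {
  list(psd = list(segmentLen = 256L, shift = 128L, fmin = 0.3, fmax = 40),
       svd_entropy = list(order = 3L, delay = 1L),
       higuchi_fd = list(kmax = 10L),
       permutation_entropy = list(order = 3L, delay = 1L),
       dfa = list(scales = NULL))
}

FEATURE_MEASURES <- c("psd", "svd_entropy", "higuchi_fd",
                      "permutation_entropy", "dfa", "moments")

#' Assemble the classifier input table
#'
#' Computes the selected measures for every epoch and channel and
#' concatenates them horizontally: the PSD contributes one column per
#' retained frequency bin per channel, each scalar measure one column per
#' channel, and the moments four per channel (16 in total for the four
#' canonical channels). Column names follow
#' `"{channel}::{measure}[::{bin}]"`; labels are copied through. Any
#' non-finite feature value (after the moment imputation rules) raises an
#' error naming the epoch, channel and measure.
#'
#' @param epochs an [EpochSet-class].
#' @param measures character vector of measure names among `psd`,
#'   `svd_entropy`, `higuchi_fd`, `permutation_entropy`, `dfa`, `moments`,
#'   or `"all"`.
#' @param params nested parameter list, see [defaultFeatureParams()].
#' @return A [SleepFeatureTable-class] with one row per epoch.
#' @export
buildFeatureTable <- function(epochs, measures = "all",
                              params = defaultFeatureParams()) {
  stopifnot(is(epochs, "EpochSet"))
  if (identical(measures, "all")) measures <- FEATURE_MEASURES
  bad <- setdiff(measures, FEATURE_MEASURES)
  if (length(bad))
    stop("unknown measure(s): ", paste(sQuote(bad), collapse = ", "))
  nEp <- nEpochs(epochs)
  if (!nEp) stop("empty EpochSet: no epochs to featurise")
  chans <- channelNames(epochs)
  fs <- epochs@fs
  p <- utils::modifyList(defaultFeatureParams(), params)

  ## fixed column layout, derived from the configuration
  psdFreq <- NULL
  if ("psd" %in% measures) {
    probe <- do.call(welchPsd, c(list(x = epochs@data[1, 1, ], fs = fs),
                                 p$psd))
    psdFreq <- probe$freq
  }
  colsFor <- function(ch, m) switch(m,
    psd = paste0(ch, "::psd::", sprintf("%.6g", psdFreq)),
    moments = paste0(ch, "::", c("mean", "sd", "skewness", "kurtosis")),
    paste0(ch, "::", m))
  colNames <- unlist(lapply(measures,
                            function(m) unlist(lapply(chans, colsFor, m = m))))
  out <- matrix(NA_real_, nrow = nEp, ncol = length(colNames),
                dimnames = list(NULL, colNames))

  for (e in seq_len(nEp)) {
    for (ci in seq_along(chans)) {
      x <- epochs@data[e, ci, ]
      for (m in measures) {
        vals <- switch(m,
          psd = do.call(welchPsd, c(list(x = x, fs = fs), p$psd))$psd,
          svd_entropy = do.call(svdEntropy, c(list(x = x), p$svd_entropy)),
          higuchi_fd = do.call(higuchiFd, c(list(x = x), p$higuchi_fd)),
          permutation_entropy = do.call(permutationEntropy,
                                        c(list(x = x),
                                          p$permutation_entropy)),
          dfa = do.call(dfa, c(list(x = x), p$dfa)),
          moments = signalMoments(x))
        if (any(!is.finite(vals)))
          stop("non-finite feature: epoch ", e, ", channel ",
               sQuote(chans[ci]), ", measure ", sQuote(m))
        out[e, colsFor(chans[ci], m)] <- vals
      }
    }
  }
  sleepFeatureTable(out, labels = epochLabels(epochs),
                    rawLabels = rawLabels(epochs))
}
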