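# Independent brute-force reference implementations of the feature
# estimators, written as naive loops straight from the defining formulas.
# They deliberately share no code with the package internals.

oracleWelch <- function(x, fs, M, S, fmin, fmax) {
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(M) - 1) / (M - 1))
  W <- sum(w^2)
  K <- (length(x) - M) %/% S + 1
  nb <- M %/% 2 + 1
  Sx <- numeric(nb)
  for (k in seq_len(K)) {
    seg <- x[(k - 1) * S + seq_len(M)]
    for (i in seq_len(nb)) {            # v = (i-1)/M
      mm <- 0:(M - 1)
      X <- sum(seg * w * exp(-2i * pi * (i - 1) * mm / M))
      Sx[i] <- Sx[i] + Mod(X)^2 / W     # periodogram P_k(v)
    }
  }
  Sx <- Sx / K                          # average over periodograms
  scale <- rep(2 / fs, nb)
  scale[1] <- 1 / fs
  if (M %% 2 == 0) scale[nb] <- 1 / fs
  freq <- (seq_len(nb) - 1) * fs / M
  keep <- freq >= fmin & freq <= fmax
  list(freq = freq[keep], psd = (Sx * scale)[keep])
}

oracleSvdEntropy <- function(x, d, tau) {
  nr <- length(x) - (d - 1) * tau
  Y <- matrix(0, nr, d)
  for (i in seq_len(nr))
    for (j in seq_len(d))
      Y[i, j] <- x[i + (j - 1) * tau]
  s <- svd(Y)$d
  if (sum(s) == 0) return(0)
  p <- s / sum(s)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracleHiguchi <- function(x, kmax) {
  N <- length(x)
  L <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      nI <- floor((N - m) / k)
      tot <- 0
      for (i in seq_len(nI))
        tot <- tot + abs(x[m + i * k] - x[m + (i - 1) * k])
      Lm[m] <- tot * (N - 1) / (nI * k) / k
    }
    L[k] <- mean(Lm)
  }
  if (all(L == 0)) return(1.0)
  unname(coef(lm(log(L) ~ log(1 / seq_len(kmax))))[2])
}

oraclePermEntropy <- function(x, D, tau) {
  nr <- length(x) - (D - 1) * tau
  pats <- character(nr)
  for (i in seq_len(nr)) {
    v <- x[i + (seq_len(D) - 1) * tau]
    pats[i] <- paste(rank(v, ties.method = "first"), collapse = "-")
  }
  p <- as.numeric(table(pats)) / nr
  -sum(p * log2(p))
}

oracleDfa <- function(x, scales) {
  N <- length(x)
  y <- cumsum(x - mean(x))
  Fn <- numeric(length(scales))
  for (si in seq_along(scales)) {
    n <- scales[si]
    nw <- floor(N / n)
    ss <- 0
    for (wdx in seq_len(nw)) {
      idx <- ((wdx - 1) * n + 1):(wdx * n)
      fit <- lm(y[idx] ~ idx)
      ss <- ss + sum(residuals(fit)^2)
    }
    Fn[si] <- sqrt(ss / (nw * n))
  }
  unname(coef(lm(log(Fn) ~ log(scales)))[2])
}

oracleMoments <- function(x) {
  N <- length(x)
  mu <- sum(x) / N
  sigma <- sqrt(sum((x - mu)^2) / N)
  c(mean = mu, sd = sigma,
    skewness = sum((x - mu)^3) / ((N - 1) * sigma^3),
    kurtosis = (sum((x - mu)^4) / N) / sigma^4)
}
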