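# Independent oracles used to cross-check the pipeline implementations.
# These deliberately use different algorithms from the package code paths
# (Floyd-Warshall instead of BFS, direct summation instead of FFT).

# all-pairs shortest paths by Floyd-Warshall
oracleFloydWarshall <- function(a) {
  n <- nrow(a)
  D <- ifelse(a > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# graph metrics straight from the defining formulas, using FW distances
oracleGlobalEfficiency <- function(a) {
  n <- nrow(a)
  D <- oracleFloydWarshall(a)
  tot <- 0
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) if (j != i && is.finite(D[i, j])) s <- s + 1 / D[i, j]
    tot <- tot + s / (n - 1)
  }
  tot / n
}

oracleNodalEfficiency <- function(a) {
  n <- nrow(a)
  D <- oracleFloydWarshall(a)
  vapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(n)) if (j != i && is.finite(D[i, j])) s <- s + 1 / D[i, j]
    s / (n - 1)
  }, numeric(1))
}

oracleLocalEfficiency <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    Dsub <- oracleFloydWarshall(a[nb, nb, drop = FALSE])
    s <- 0
    for (j in seq_len(k)) for (h in seq_len(k)) {
      if (j == h) next
      if (is.finite(Dsub[j, h]))
        s <- s + (a[i, nb[j]] * a[i, nb[h]])^(1 / 3) / Dsub[j, h]
    }
    s / (k * (k - 1))
  }, numeric(1))
}

oracleClustering <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    k <- sum(a[i, ])
    if (k < 2) return(0)
    tri <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j < h && a[i, j] > 0 && a[i, h] > 0 && a[j, h] > 0) tri <- tri + 1
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

# adjacency matrix of the g-th edge pattern on n nodes (g in 0..2^(n(n-1)/2)-1)
enumGraph <- function(n, g) {
  npairs <- n * (n - 1) / 2
  bits <- as.integer(intToBits(g))[seq_len(npairs)]
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- bits
  a + t(a)
}

# band iCOH by direct summation: explicit DFT loops, trial-summed
# cross-spectra, standard coherency normalization, plain bin average
oracleIcohBand <- function(wins, fs, band) {
  nt <- dim(wins)[1]; nch <- dim(wins)[2]; ns <- dim(wins)[3]
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(ns) - 1) / ns))
  nf <- ns %/% 2 + 1
  freqs <- (seq_len(nf) - 1) * fs / ns
  X <- array(0i, dim = c(nt, nch, nf))
  for (tr in seq_len(nt)) for (ch in seq_len(nch)) for (f in seq_len(nf)) {
    s <- 0i
    for (t in seq_len(ns))
      s <- s + wins[tr, ch, t] * w[t] *
        exp(-2i * pi * (f - 1) * (t - 1) / ns)
    X[tr, ch, f] <- s
  }
  bins <- which(freqs >= band[1] & freqs <= band[2])
  out <- matrix(0, nch, nch)
  for (i in seq_len(nch)) for (j in seq_len(nch)) {
    if (i == j) next
    acc <- 0
    for (f in bins) {
      Sij <- sum(X[, i, f] * Conj(X[, j, f])) / nt
      Sii <- sum(X[, i, f] * Conj(X[, i, f])) / nt
      Sjj <- sum(X[, j, f] * Conj(X[, j, f])) / nt
      acc <- acc + Im(Sij / sqrt(Re(Sii) * Re(Sjj)))
    }
    out[i, j] <- acc / length(bins)
  }
  out
}

# small epoched-array builder; default epoch spans [-1, 1.5) s so both
# default analysis windows fit (data must have 2.5*fs samples then)
makeEpochs <- function(data, fs = 256, channels = NULL,
                       t0 = as.integer(fs) + 1L,
                       preWindow = c(-1, 0), postWindow = c(0.25, 1.25)) {
  if (is.null(channels)) channels <- paste0("ch", seq_len(dim(data)[2]))
  new("EpochSet", data = data, fs = fs, channels = channels,
      t0 = as.integer(t0), preWindow = preWindow, postWindow = postWindow)
}
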