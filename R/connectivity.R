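#' @include AllClasses.R
NULL

## periodic Hann taper
.hann <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' Per-trial spectra and trial-averaged cross-spectral matrix
#'
#' Computes the complex spectrum of every trial and channel over the full
#' window (single segment, Hann taper) and the cross-spectral matrix
#' S_ij(f) = (1/N) sum_trials X_i(f) conj(X_j(f)), where N is the number of
#' trials. Coherence is undefined from a single realization, so at least two
#' trials are required.
#'
#' @param wins trials x channels x samples numeric array (one analysis
#'   window, e.g. from [extractWindows()]).
#' @param fs sampling rate in Hz.
#' @param channels channel labels (default ch1..chK).
#' @param taper "hann" (default) or "none".
#' @return a [SpectralEstimate-class]; the frequency grid spans 0..fs/2 with
#'   resolution fs/samples (1 Hz for a 1-s window).
#' @export
crossSpectra <- function(wins, fs, channels = NULL, taper = c("hann", "none")) {
  taper <- match.arg(taper)
  d <- dim(wins)
  if (length(d) != 3L) stop("wins must be trials x channels x samples")
  nt <- d[1]; nch <- d[2]; ns <- d[3]
  if (nt < 2L)
    stop("coherence is undefined from a single trial; need at least 2")
  if (is.null(channels)) channels <- paste0("ch", seq_len(nch))
  w <- if (taper == "hann") .hann(ns) else rep(1, ns)
  ## FFT all trial x channel signals at once: samples in rows
  flat <- matrix(aperm(wins, c(3, 1, 2)), nrow = ns) * w
  spec <- stats::mvfft(flat)                 # ns x (nt*nch)
  nf <- ns %/% 2L + 1L
  freqs <- (seq_len(nf) - 1) * fs / ns
  X <- aperm(array(spec[seq_len(nf), ], dim = c(nf, nt, nch)), c(2, 3, 1))
  S <- array(0i, dim = c(nch, nch, nf))
  for (f in seq_len(nf)) {
    Xf <- matrix(X[, , f], nrow = nt)        # trials x channels
    S[, , f] <- crossprod(Xf, Conj(Xf)) / nt # S_ij = mean X_i conj(X_j)
  }
  new("SpectralEstimate", X = X, S = S, nTrials = as.integer(nt),
      freqs = freqs, channels = channels)
}

#' Complex coherency
#'
#' Normalizes the cross-spectral matrix to coherency
#' C_ij(f) = S_ij(f) / sqrt(S_ii(f) S_jj(f)), so |C_ij| <= 1, C_ii = 1, and
#' the phase of C_ij carries the time-lag structure between channels. The
#' imaginary part of C is insensitive to instantaneous (zero-lag) mixing,
#' which is why it is used for sensor-level functional connectivity.
#'
#' @param s a [SpectralEstimate-class].
#' @param window optional window label ("pre"/"post") recorded in the result.
#' @return a [CoherenceStack-class].
#' @export
coherency <- function(s, window = "") {
  stopifnot(is(s, "SpectralEstimate"))
  nch <- length(s@channels); nf <- length(s@freqs)
  C <- array(0i, dim = c(nch, nch, nf))
  for (f in seq_len(nf)) {
    Sf <- s@S[, , f]
    auto <- Re(diag(Sf))
    if (any(auto <= 0)) {
      bad <- which(auto <= 0)[1]
      stop(sprintf("zero auto-spectrum for channel %s at %.3g Hz",
                   s@channels[bad], s@freqs[f]))
    }
    norm <- sqrt(auto)
    Cf <- Sf / (norm %o% norm)
    ## clamp round-off excursions above unit magnitude
    m <- Mod(Cf)
    over <- m > 1
    if (any(over)) Cf[over] <- Cf[over] / m[over]
    C[, , f] <- Cf
  }
  new("CoherenceStack", coherency = C, freqs = s@freqs,
      channels = s@channels, window = as.character(window),
      normalization = "C_ij = S_ij / sqrt(S_ii S_jj)")
}

#' Band-aggregated imaginary coherency (iCOH)
#'
#' Averages the imaginary part of the coherency over the frequency bins
#' falling in `[low, high]` (inclusive). The result is antisymmetric
#' (icoh_ij = -icoh_ji) with zero diagonal; its magnitude is used for edge
#' ranking downstream.
#'
#' @param cs a [CoherenceStack-class].
#' @param band numeric length-2 `c(low, high)` in Hz.
#' @return channels x channels real matrix.
#' @export
icohBand <- function(cs, band) {
  stopifnot(is(cs, "CoherenceStack"), length(band) == 2L)
  bins <- which(cs@freqs >= band[1] & cs@freqs <= band[2])
  if (length(bins) == 0L)
    stop("no frequency bins inside the band [", band[1], ", ", band[2], "] Hz")
  im <- Im(cs@coherency[, , bins, drop = FALSE])
  out <- apply(im, c(1, 2), mean)
  dimnames(out) <- list(cs@channels, cs@channels)
  ## enforce exact antisymmetry and zero diagonal against round-off
  out <- (out - t(out)) / 2
  diag(out) <- 0
  out
}

#' Per-window, per-band iCOH matrices for one subject
#'
#' Convenience wrapper: extracts the pre/post analysis windows, estimates
#' cross-spectra and coherency per window, and aggregates iCOH per band.
#'
#' @param e an [EpochSet-class].
#' @param bands data.frame with columns name, low, high (default
#'   [defaultBands()]).
#' @return nested list `result[[window]][[band]]` of antisymmetric
#'   channels x channels matrices, windows "pre" and "post".
#' @export
icohMatrices <- function(e, bands = defaultBands()) {
  stopifnot(is(e, "EpochSet"))
  wins <- extractWindows(e)
  out <- list()
  for (w in names(wins)) {
    se <- crossSpectra(wins[[w]], samplingRate(e), channelNames(e))
    cs <- coherency(se, window = w)
    out[[w]] <- lapply(stats::setNames(seq_len(nrow(bands)), bands$name),
                       function(b) icohBand(cs, c(bands$low[b], bands$high[b])))
  }
  out
}

#' Write labeled connectivity matrices
#'
#' Serializes per-window, per-band iCOH matrices as labeled tab-delimited
#' files (`<id>_<window>_<band>.tsv`) plus a manifest.
#'
#' @param icohList output of [icohMatrices()].
#' @param id subject identifier used in filenames.
#' @param dir output directory.
#' @return manifest data.frame invisibly.
#' @export
writeConnectivity <- function(icohList, id, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- list()
  for (w in names(icohList)) for (b in names(icohList[[w]])) {
    fn <- sprintf("%s_%s_%s.tsv", id, w, b)
    utils::write.table(icohList[[w]][[b]], file.path(dir, fn), sep = "\t",
                       quote = FALSE, col.names = NA)
    rows[[length(rows) + 1L]] <- data.frame(id = id, window = w, band = b,
                                            file = fn)
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, sprintf("%s_manifest.tsv", id)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
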