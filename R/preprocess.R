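#' @include AllClasses.R
NULL

#' Construct a continuous recording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channels channel labels (defaults to rownames of `data`).
#' @return an [EEGRecording-class].
#' @export
eegRecording <- function(data, fs, channels = rownames(data)) {
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- channels
  new("EEGRecording", data = data, fs = fs, channels = channels)
}

## zero-phase band-pass at [low, high]: 2nd-order Butterworth high-pass for
## the low edge (exact null at DC) plus a windowed-sinc FIR low-pass for the
## high edge (steep transition), both applied forward-backward.
.bandpassChannel <- function(x, fs, low, high, firTaps = 64L) {
  hp <- signal::butter(2, low / (fs / 2), type = "high")
  x <- signal::filtfilt(hp, x)
  lp <- signal::fir1(firTaps, high / (fs / 2), type = "low")
  signal::filtfilt(lp, x)
}

## anti-aliased rate conversion: FIR low-pass at 80% of the target Nyquist,
## then exact subsampling for integer ratios, cubic spline otherwise.
.resampleChannel <- function(x, fs, targetFs) {
  if (targetFs == fs) return(x)
  lp <- signal::fir1(96, 0.8 * targetFs / fs, type = "low")
  x <- signal::filtfilt(lp, x)
  ratio <- fs / targetFs
  n <- length(x)
  if (abs(ratio - round(ratio)) < 1e-9) {
    x[seq(1, n, by = round(ratio))]
  } else {
    tOld <- (seq_len(n) - 1) / fs
    tNew <- seq(0, tOld[n], by = 1 / targetFs)
    stats::spline(tOld, x, xout = tNew)$y
  }
}

#' Band-pass filter and resample a continuous recording
#'
#' Resamples to `targetFs` (anti-aliased) and band-pass filters to
#' `[low, high]` Hz. All filtering is zero-phase (forward-backward), so event
#' latencies are not delayed. The band-pass is a 2nd-order Butterworth
#' high-pass (removing DC exactly) combined with a windowed-sinc FIR low-pass
#' whose transition provides at least 40 dB stopband attenuation outside the
#' band at the working rate.
#'
#' @param rec an [EEGRecording-class].
#' @param low,high band edges in Hz; defaults 1 and 80.
#' @param targetFs target sampling rate; default 256 Hz.
#' @return a filtered [EEGRecording-class] sampled at `targetFs`.
#' @export
bandpassResample <- function(rec, low = 1, high = 80, targetFs = 256) {
  stopifnot(is(rec, "EEGRecording"))
  if (low <= 0 || low >= high)
    stop("need 0 < low < high")
  if (high >= targetFs / 2)
    stop("high edge (", high, " Hz) must be below the target Nyquist (",
         targetFs / 2, " Hz)")
  if (high >= rec@fs / 2)
    stop("high edge must be below the original Nyquist")
  if (targetFs > rec@fs) stop("targetFs must not exceed the original rate")
  out <- t(apply(rec@data, 1, function(x) {
    x <- .resampleChannel(x, rec@fs, targetFs)
    .bandpassChannel(x, targetFs, low, high)
  }))
  eegRecording(out, targetFs, rec@channels)
}

#' Extract epochs around cue events
#'
#' Cuts one trial per event spanning `span` seconds around the cue
#' (half-open sample windows, cue at relative time 0). Events whose epoch
#' would extend past the recording edge are dropped with a warning.
#'
#' @param rec an [EEGRecording-class].
#' @param events integer vector of cue sample indices (1-based).
#' @param span length-2 seconds around the cue; default c(-2, 5).
#' @param preWindow,postWindow analysis windows in seconds (half-open),
#'   defaults `[-1, 0)` and `[0.25, 1.25)`.
#' @return an [EpochSet-class]; zero events give an empty EpochSet.
#' @export
epochRecording <- function(rec, events, span = c(-2, 5),
                           preWindow = c(-1, 0), postWindow = c(0.25, 1.25)) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@fs
  nsamp <- as.integer(round(diff(span) * fs))
  t0 <- as.integer(round(-span[1] * fs)) + 1L
  nrec <- ncol(rec@data)
  events <- as.integer(events)
  start <- events - t0 + 1L
  keep <- start >= 1L & (start + nsamp - 1L) <= nrec
  if (any(!keep))
    warning(sum(!keep), " event(s) too close to the recording edge; ",
            "trial(s) dropped")
  events <- events[keep]
  arr <- array(0, dim = c(length(events), length(rec@channels), nsamp))
  for (i in seq_along(events)) {
    s0 <- events[i] - t0 + 1L
    arr[i, , ] <- rec@data[, s0:(s0 + nsamp - 1L), drop = FALSE]
  }
  new("EpochSet", data = arr, fs = fs, channels = rec@channels, t0 = t0,
      preWindow = preWindow, postWindow = postWindow)
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the channel mean is zero at every sample. Idempotent.
#'
#' @param e an [EpochSet-class] with at least two channels.
#' @return the re-referenced [EpochSet-class].
#' @export
commonAverageReference <- function(e) {
  stopifnot(is(e, "EpochSet"))
  d <- e@data
  if (dim(d)[2] < 2L)
    stop("common average reference undefined for a single channel")
  m <- apply(d, c(1, 3), mean)          # trials x samples
  for (ch in seq_len(dim(d)[2])) d[, ch, ] <- d[, ch, ] - m
  methods::initialize(e, data = d)
}

#' Left/right homolog map for 10-10 labels
#'
#' Maps each channel label to its hemispheric homolog: odd digits pair with
#' the next even digit (C3<->C4, P9<->P10, ...); midline labels (z suffix)
#' map to themselves. The shipped file `extdata/montage64_homologs.tsv`
#' records the map for the default 64-channel montage.
#'
#' @param labels character channel labels.
#' @return named character vector, `labels -> homolog label`.
#' @export
homologMap <- function(labels) {
  m <- regmatches(labels, regexec("^([A-Za-z]+?)(z|[0-9]+)$", labels))
  out <- vapply(seq_along(labels), function(i) {
    parts <- m[[i]]
    if (length(parts) != 3L)
      stop("cannot parse channel label: ", labels[i])
    if (parts[3] == "z") return(labels[i])
    k <- as.integer(parts[3])
    paste0(parts[2], if (k %% 2 == 1L) k + 1L else k - 1L)
  }, character(1))
  names(out) <- labels
  out
}

#' Flip hemispheres so the left hemisphere is contralateral
#'
#' If the performing (affected) hand is the left, each channel's data is
#' swapped with its hemispheric homolog; if right, the data are returned
#' unchanged. After this step the left hemisphere is always contralateral to
#' the performing hand, making lateralized features comparable across
#' subjects.
#'
#' @param e an [EpochSet-class].
#' @param performingHand "left" or "right".
#' @return the (possibly flipped) [EpochSet-class].
#' @export
flipHemispheres <- function(e, performingHand) {
  stopifnot(is(e, "EpochSet"))
  performingHand <- match.arg(performingHand, c("left", "right"))
  if (performingHand == "right") return(e)
  hm <- homologMap(e@channels)
  idx <- match(hm, e@channels)
  if (anyNA(idx)) {
    missing <- e@channels[is.na(idx)]
    stop("no homolog present in the montage for channel(s): ",
         paste(missing, collapse = ", "))
  }
  methods::initialize(e, data = e@data[, idx, , drop = FALSE])
}

#' Muscle-artifact removal hook
#'
#' Pass-through interface where an external artifact cleaner (e.g. an
#' ICA-based remover) may be plugged in. The default is the identity:
#' synthetic cohorts carry no muscle artifacts, and artifact decomposition is
#' delegated to external tooling.
#'
#' @param e an [EpochSet-class].
#' @param cleaner function(EpochSet) -> EpochSet, or NULL for the identity.
#' @return an [EpochSet-class].
#' @export
artifactHook <- function(e, cleaner = NULL) {
  stopifnot(is(e, "EpochSet"))
  if (is.null(cleaner)) return(e)
  out <- cleaner(e)
  stopifnot(is(out, "EpochSet"))
  out
}

#' Extract the pre- and post-task analysis windows
#'
#' Cuts the two half-open analysis windows out of each trial. Both windows
#' have identical sample counts (1 s at the sampling rate for the default
#' windows).
#'
#' @param e an [EpochSet-class].
#' @return list(pre, post) of trials x channels x samples arrays.
#' @export
extractWindows <- function(e) {
  stopifnot(is(e, "EpochSet"))
  nsamp <- dim(e@data)[3]
  pre <- .windowIndices(e@t0, e@fs, e@preWindow, nsamp)
  post <- .windowIndices(e@t0, e@fs, e@postWindow, nsamp)
  list(pre = e@data[, , pre, drop = FALSE],
       post = e@data[, , post, drop = FALSE])
}

#' Read a delimited recording and event table
#'
#' `readRecording()` reads a delimited numeric matrix (samples x channels,
#' header row of channel labels, or a sidecar label file with one label per
#' line). `readEvents()` reads a two-column delimited table (sample, code).
#'
#' @param file path to the delimited matrix.
#' @param fs sampling rate in Hz.
#' @param channelFile optional sidecar file of channel labels.
#' @param sep field separator.
#' @return `readRecording()` an [EEGRecording-class]; `readEvents()` a
#'   data.frame (sample, code).
#' @export
readRecording <- function(file, fs, channelFile = NULL, sep = "\t") {
  hasHeader <- is.null(channelFile)
  df <- utils::read.table(file, header = hasHeader, sep = sep,
                          check.names = FALSE)
  labels <- if (hasHeader) names(df) else readLines(channelFile)
  eegRecording(t(as.matrix(df)), fs, labels)
}

#' @rdname readRecording
#' @export
readEvents <- function(file, sep = "\t") {
  ev <- utils::read.table(file, header = TRUE, sep = sep)
  if (!all(c("sample", "code") %in% names(ev)))
    stop("event table needs 'sample' and 'code' columns")
  ev
}
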