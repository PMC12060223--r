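#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Core data containers
## ---------------------------------------------------------------------------

#' Continuous multichannel EEG recording
#'
#' A continuous (unepoched) recording: a channels x samples numeric matrix in
#' microvolts, its sampling rate and channel labels. This is the input to
#' [bandpassResample()] and [epochRecording()].
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot channels character vector of unique channel labels (10-10 names).
#' @export
setClass("EEGRecording",
  representation(data = "matrix", fs = "numeric", channels = "character"),
  validity = function(object) {
    msg <- NULL
    if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
    if (length(object@fs) != 1L || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    if (nrow(object@data) != length(object@channels))
      msg <- c(msg, "nrow(data) must equal length(channels)")
    if (anyDuplicated(object@channels))
      msg <- c(msg, "channel labels must be unique")
    if (is.null(msg)) TRUE else msg
  }
)

#' Epoched multichannel EEG
#'
#' Per-subject epoched EEG: a trials x channels x samples array, sampling
#' rate, channel labels, the cue-onset sample index within each trial, and the
#' analysis windows. Windows are half-open `[start, end)` in seconds relative
#' to the cue; the defaults are the pre-task baseline `[-1, 0)` and the
#' post-task window `[0.25, 1.25)` (movement-preparation latency after the
#' cue).
#'
#' @slot data numeric array, trials x channels x samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot channels character vector of unique channel labels.
#' @slot t0 1-based sample index of the cue within each trial.
#' @slot preWindow,postWindow numeric length-2, seconds relative to the cue,
#'   half-open.
#' @export
setClass("EpochSet",
  representation(data = "array", fs = "numeric", channels = "character",
                 t0 = "integer", preWindow = "numeric", postWindow = "numeric"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@data)
    if (length(d) != 3L)
      return("data must be a trials x channels x samples array")
    if (d[2] != length(object@channels))
      msg <- c(msg, "dim(data)[2] must equal length(channels)")
    if (anyDuplicated(object@channels))
      msg <- c(msg, "channel labels must be unique")
    if (length(object@fs) != 1L || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive number")
    if (length(object@t0) != 1L || object@t0 < 1L || object@t0 > max(d[3], 1L))
      msg <- c(msg, "t0 must be a sample index inside the epoch")
    for (w in list(object@preWindow, object@postWindow)) {
      if (length(w) != 2L || w[1] >= w[2])
        msg <- c(msg, "windows must be increasing length-2 numerics")
    }
    ## windows must lie inside the epoch span (only checkable with samples)
    if (d[3] > 0L) {
      span <- c(1L - object@t0, d[3] - object@t0 + 1L) / object@fs
      for (w in list(object@preWindow, object@postWindow)) {
        if (length(w) == 2L && (w[1] < span[1] - 1e-9 || w[2] > span[2] + 1e-9))
          msg <- c(msg, "analysis windows must lie inside the epoch span")
      }
    }
    if (is.null(msg)) TRUE else msg
  }
)

## ---------------------------------------------------------------------------
## Synthetic-cohort specification
## ---------------------------------------------------------------------------

#' Specification of a synthetic EEG cohort
#'
#' Defines the generative model for [generateCohort()]: montage, protocol
#' (trials, epoch span, sampling rate), frequency bands, planted phase-lagged
#' couplings (which create nonzero imaginary coherency), planted ERD effects
#' (post/pre band-power ratios), and the outcome model mapping planted feature
#' magnitudes to UL-FMA scores. Use the [cohortSpec()] constructor.
#'
#' @slot nSubjectsPerGroup subjects per group (stroke, control).
#' @slot channels channel labels used for the montage.
#' @slot fs sampling rate in Hz.
#' @slot nTrials trials per subject.
#' @slot epochWindow epoch span in seconds around the cue.
#' @slot seed integer seed; identical seed + spec gives an identical cohort.
#' @slot bands data.frame with columns name, low, high (Hz).
#' @slot plantedEdges data.frame with columns chi, chj, band, phase (radians),
#'   strength (0..1), window ("pre"/"post"/"both"), group
#'   ("both"/"stroke"/"control").
#' @slot erdEffects data.frame with columns channel, band, ratio (post/pre
#'   band-power ratio, > 0), group.
#' @slot outcomeModel list(intercept, coefficients = named numeric over
#'   planted-feature labels, noiseSD).
#' @slot subjectSD lognormal SD of per-subject scaling of planted effect
#'   magnitudes (inter-subject variability; free parameter).
#' @slot commonSourceStrength amplitude of a zero-lag common source mixed into
#'   all channels (volume-conduction surrogate; 0 disables).
#' @slot backgroundSD per-channel white background-noise SD.
#' @slot sourceAmplitude amplitude of each planted oscillator.
#' @export
setClass("CohortSpec",
  representation(nSubjectsPerGroup = "integer", channels = "character",
                 fs = "numeric", nTrials = "integer", epochWindow = "numeric",
                 seed = "integer", bands = "data.frame",
                 plantedEdges = "data.frame", erdEffects = "data.frame",
                 outcomeModel = "list", subjectSD = "numeric",
                 commonSourceStrength = "numeric", backgroundSD = "numeric",
                 sourceAmplitude = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@nSubjectsPerGroup < 1L)
      msg <- c(msg, "need at least one subject per group")
    if (object@nTrials < 1L) msg <- c(msg, "need at least one trial")
    if (length(object@epochWindow) != 2L ||
        object@epochWindow[1] >= object@epochWindow[2])
      msg <- c(msg, "epochWindow must be an increasing length-2 numeric")
    b <- object@bands
    if (nrow(b) > 0 && (any(b$low <= 0) || any(b$low >= b$high) ||
                        any(b$high >= object@fs / 2)))
      msg <- c(msg, "bands must satisfy 0 < low < high < fs/2")
    pe <- object@plantedEdges
    if (nrow(pe) > 0) {
      if (any(pe$strength < 0 | pe$strength > 1))
        msg <- c(msg, "coupling strength must lie in [0, 1]")
      if (!all(pe$band %in% b$name))
        msg <- c(msg, "planted edge bands must name a configured band")
      if (!all(c(pe$chi, pe$chj) %in% object@channels))
        msg <- c(msg, "planted edge channels must be in the montage")
      if (!all(pe$window %in% c("pre", "post", "both")))
        msg <- c(msg, "edge window must be pre, post or both")
    }
    ee <- object@erdEffects
    if (nrow(ee) > 0) {
      if (any(ee$ratio <= 0))
        msg <- c(msg, "post/pre power ratio must be > 0")
      if (!all(ee$band %in% b$name))
        msg <- c(msg, "ERD bands must name a configured band")
      if (!all(ee$channel %in% object@channels))
        msg <- c(msg, "ERD channels must be in the montage")
    }
    om <- object@outcomeModel
    if (!all(c("intercept", "coefficients", "noiseSD") %in% names(om)))
      msg <- c(msg, "outcomeModel needs intercept, coefficients, noiseSD")
    if (is.null(msg)) TRUE else msg
  }
)

#' One synthetic subject
#'
#' A subject's identifier, group, performing/affected hand, UL-FMA score and
#' epoched EEG.
#'
#' @slot id subject identifier.
#' @slot group "stroke" or "control".
#' @slot hand performing (affected) hand, "left" or "right".
#' @slot ulFMA upper-limb Fugl-Meyer score in [0, 66].
#' @slot epochs an [EpochSet-class].
#' @export
setClass("SubjectRecord",
  representation(id = "character", group = "character", hand = "character",
                 ulFMA = "numeric", epochs = "EpochSet"),
  validity = function(object) {
    msg <- NULL
    if (!object@group %in% c("stroke", "control"))
      msg <- c(msg, "group must be stroke or control")
    if (!object@hand %in% c("left", "right"))
      msg <- c(msg, "hand must be left or right")
    if (object@ulFMA < 0 || object@ulFMA > 66)
      msg <- c(msg, "ulFMA must lie in [0, 66]")
    if (is.null(msg)) TRUE else msg
  }
)

## ---------------------------------------------------------------------------
## Spectral / connectivity containers
## ---------------------------------------------------------------------------

#' Trial spectra and cross-spectral matrix
#'
#' Per-trial complex spectra X (trials x channels x frequencies) and the
#' trial-averaged cross-spectral matrix S (channels x channels x frequencies),
#' S_ij(f) = (1/N) sum_trials X_i(f) conj(X_j(f)). S is Hermitian at every
#' frequency with real nonnegative diagonal.
#'
#' @slot X complex array, trials x channels x frequencies.
#' @slot S complex array, channels x channels x frequencies.
#' @slot nTrials number of trials averaged.
#' @slot freqs frequency grid in Hz.
#' @slot channels channel labels.
#' @export
setClass("SpectralEstimate",
  representation(X = "array", S = "array", nTrials = "integer",
                 freqs = "numeric", channels = "character"),
  validity = function(object) {
    msg <- NULL
    dS <- dim(object@S)
    if (length(dS) != 3L || dS[1] != dS[2])
      return("S must be a channels x channels x frequencies array")
    if (dS[1] != length(object@channels))
      msg <- c(msg, "S dimensions must match channels")
    if (dS[3] != length(object@freqs))
      msg <- c(msg, "S third dimension must match freqs")
    if (is.null(msg)) TRUE else msg
  }
)

#' Complex coherency stack
#'
#' Coherency C_ij(f) = S_ij(f) / sqrt(S_ii(f) S_jj(f)) per channel pair and
#' frequency, with the frequency grid, channel labels and the analysis-window
#' label. The imaginary part aggregated over a band (iCOH) is obtained with
#' [icohBand()].
#'
#' @slot coherency complex array, channels x channels x frequencies.
#' @slot freqs frequency grid in Hz.
#' @slot channels channel labels.
#' @slot window analysis-window label ("pre" or "post"), or "" if unset.
#' @slot normalization character note recording the normalization used.
#' @export
setClass("CoherenceStack",
  representation(coherency = "array", freqs = "numeric",
                 channels = "character", window = "character",
                 normalization = "character"),
  validity = function(object) {
    d <- dim(object@coherency)
    msg <- NULL
    if (length(d) != 3L || d[1] != d[2])
      return("coherency must be channels x channels x frequencies")
    if (d[1] != length(object@channels))
      msg <- c(msg, "coherency dimensions must match channels")
    if (d[3] != length(object@freqs))
      msg <- c(msg, "coherency third dimension must match freqs")
    if (max(Mod(object@coherency), 0) > 1 + 1e-9)
      msg <- c(msg, "|coherency| must not exceed 1 (+1e-9)")
    if (is.null(msg)) TRUE else msg
  }
)

## ---------------------------------------------------------------------------
## Graph container
## ---------------------------------------------------------------------------

#' Binary graph from proportional thresholding
#'
#' Binary symmetric adjacency with zero diagonal obtained by retaining the
#' top fraction of edges ranked by |connectivity|; see
#' [thresholdTopFraction()].
#'
#' @slot a integer 0/1 adjacency matrix, symmetric, zero diagonal.
#' @slot fraction fraction of edges retained.
#' @slot channels node (channel) labels.
#' @export
setClass("ThresholdedGraph",
  representation(a = "matrix", fraction = "numeric", channels = "character"),
  validity = function(object) {
    a <- object@a
    msg <- NULL
    if (nrow(a) != ncol(a)) return("adjacency must be square")
    if (!all(a %in% c(0L, 1L))) msg <- c(msg, "adjacency must be binary")
    if (any(a != t(a))) msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(a) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
    if (length(object@channels) && length(object@channels) != nrow(a))
      msg <- c(msg, "channel labels must match adjacency dimension")
    if (object@fraction <= 0 || object@fraction > 1)
      msg <- c(msg, "fraction must lie in (0, 1]")
    if (is.null(msg)) TRUE else msg
  }
)

## ---------------------------------------------------------------------------
## Prediction container
## ---------------------------------------------------------------------------

#' Leave-one-out prediction result
#'
#' Per-subject actual and LOO-predicted UL-FMA scores plus summary metrics
#' (both RMSE denominator conventions, R-squared, adjusted R-squared, Pearson
#' correlation) and the model formula used.
#'
#' @slot table data.frame with columns subject, actual, predicted.
#' @slot metrics named numeric: rmse_n, rmse_n1, r2, adj_r2, correlation.
#' @slot formula character model formula.
#' @export
setClass("PredictionResult",
  representation(table = "data.frame", metrics = "numeric",
                 formula = "character"),
  validity = function(object) {
    msg <- NULL
    if (!all(c("subject", "actual", "predicted") %in% names(object@table)))
      msg <- c(msg, "table needs subject, actual, predicted columns")
    if (anyDuplicated(object@table$subject))
      msg <- c(msg, "one prediction per subject")
    if (is.null(msg)) TRUE else msg
  }
)

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@fs))
  cat(sprintf("  cue at sample %d; pre [%g, %g) s, post [%g, %g) s\n",
              object@t0, object@preWindow[1], object@preWindow[2],
              object@postWindow[1], object@postWindow[2]))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(paste0("CohortSpec: %d + %d subjects, %d channels @ %g Hz, ",
                     "%d trials, epoch [%g, %g] s, seed %d\n"),
              object@nSubjectsPerGroup, object@nSubjectsPerGroup,
              length(object@channels), object@fs, object@nTrials,
              object@epochWindow[1], object@epochWindow[2], object@seed))
  cat(sprintf("  %d planted edge(s), %d ERD effect(s), %d band(s)\n",
              nrow(object@plantedEdges), nrow(object@erdEffects),
              nrow(object@bands)))
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord %s (%s, %s hand), UL-FMA %.1f\n",
              object@id, object@group, object@hand, object@ulFMA))
  show(object@epochs)
})

setMethod("show", "SpectralEstimate", function(object) {
  cat(sprintf("SpectralEstimate: %d channels, %d trials, %d frequencies (%g-%g Hz)\n",
              length(object@channels), object@nTrials, length(object@freqs),
              min(object@freqs), max(object@freqs)))
})

setMethod("show", "CoherenceStack", function(object) {
  cat(sprintf("CoherenceStack (%s): %d channels, %d frequencies; %s\n",
              if (nzchar(object@window)) object@window else "window unset",
              length(object@channels), length(object@freqs),
              object@normalization))
})

setMethod("show", "ThresholdedGraph", function(object) {
  cat(sprintf("ThresholdedGraph: %d nodes, %d edges (top %.1f%% of pairs)\n",
              nrow(object@a), sum(object@a) / 2, 100 * object@fraction))
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult: %d subjects, model %s\n",
              nrow(object@table), object@formula))
  m <- object@metrics
  cat(sprintf("  RMSE %.3f (/n) %.3f (/n-1), R2 %.3f, adj R2 %.3f, r %.4f\n",
              m["rmse_n"], m["rmse_n1"], m["r2"], m["adj_r2"],
              m["correlation"]))
})
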