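#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setMethod("epochData", "EpochSet", function(x, ...) x@data)

#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x, ...) x@fs)

#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x, ...) x@fs)

#' @rdname accessors
#' @export
setMethod("channelNames", "EpochSet", function(x, ...) x@channels)

#' @rdname accessors
#' @export
setMethod("channelNames", "EEGRecording", function(x, ...) x@channels)

#' @rdname accessors
#' @export
setMethod("channelNames", "CoherenceStack", function(x, ...) x@channels)

#' @rdname accessors
#' @export
setMethod("channelNames", "ThresholdedGraph", function(x, ...) x@channels)

#' @rdname accessors
#' @export
setMethod("nTrials", "EpochSet", function(x, ...) dim(x@data)[1])

#' @rdname accessors
#' @export
setMethod("nTrials", "SpectralEstimate", function(x, ...) x@nTrials)

#' @rdname accessors
#' @export
setMethod("cueIndex", "EpochSet", function(x, ...) x@t0)

#' @rdname accessors
#' @export
setMethod("adjacency", "ThresholdedGraph", function(x, ...) x@a)

#' @rdname accessors
#' @export
setMethod("thresholdFraction", "ThresholdedGraph", function(x, ...) x@fraction)

#' @rdname accessors
#' @export
setMethod("coherencyArray", "CoherenceStack", function(x, ...) x@coherency)

#' @rdname accessors
#' @export
setMethod("freqGrid", "CoherenceStack", function(x, ...) x@freqs)

#' @rdname accessors
#' @export
setMethod("freqGrid", "SpectralEstimate", function(x, ...) x@freqs)

#' @rdname accessors
#' @export
setMethod("crossSpectrum", "SpectralEstimate", function(x, ...) x@S)

#' @rdname accessors
#' @export
setMethod("subjectId", "SubjectRecord", function(x, ...) x@id)

#' @rdname accessors
#' @export
setMethod("subjectGroup", "SubjectRecord", function(x, ...) x@group)

#' @rdname accessors
#' @export
setMethod("performingHand", "SubjectRecord", function(x, ...) x@hand)

#' @rdname accessors
#' @export
setMethod("ulFMA", "SubjectRecord", function(x, ...) x@ulFMA)

#' @rdname accessors
#' @export
setMethod("subjectEpochs", "SubjectRecord", function(x, ...) x@epochs)

#' Prediction table and metrics of a PredictionResult
#'
#' @param x a [PredictionResult-class].
#' @return `predictionTable()` returns the per-subject data.frame;
#'   `predictionSummary()` the named metric vector.
#' @export
predictionTable <- function(x) {
  stopifnot(is(x, "PredictionResult"))
  x@table
}

#' @rdname predictionTable
#' @export
predictionSummary <- function(x) {
  stopifnot(is(x, "PredictionResult"))
  x@metrics
}
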