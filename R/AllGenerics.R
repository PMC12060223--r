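#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small accessor generics used across the package's S4 classes. Prefer these
#' over direct slot access.
#'
#' @param x an object of one of the package's S4 classes.
#' @param ... further arguments for methods.
#' @return The requested component (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("epochData", function(x, ...) standardGeneric("epochData"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x, ...) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x, ...) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x, ...) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("cueIndex", function(x, ...) standardGeneric("cueIndex"))

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x, ...) standardGeneric("adjacency"))

#' @rdname accessors
#' @export
setGeneric("thresholdFraction", function(x, ...) standardGeneric("thresholdFraction"))

#' @rdname accessors
#' @export
setGeneric("coherencyArray", function(x, ...) standardGeneric("coherencyArray"))

#' @rdname accessors
#' @export
setGeneric("freqGrid", function(x, ...) standardGeneric("freqGrid"))

#' @rdname accessors
#' @export
setGeneric("crossSpectrum", function(x, ...) standardGeneric("crossSpectrum"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x, ...) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("subjectGroup", function(x, ...) standardGeneric("subjectGroup"))

#' @rdname accessors
#' @export
setGeneric("performingHand", function(x, ...) standardGeneric("performingHand"))

#' @rdname accessors
#' @export
setGeneric("ulFMA", function(x, ...) standardGeneric("ulFMA"))

#' @rdname accessors
#' @export
setGeneric("subjectEpochs", function(x, ...) standardGeneric("subjectEpochs"))
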