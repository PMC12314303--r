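#' Accessors for streamsync containers
#'
#' \code{samples} returns the channels x time signal matrix;
#' \code{samplingRate} the sampling rate in Hz; \code{channelTable} the
#' channel table; \code{sessionId} the session identifier;
#' \code{epochData} the trials x channels x time array;
#' \code{conditionLabels} the per-trial condition factor;
#' \code{exclusionMask} the trials x channels logical mask;
#' \code{envelopeValues} the envelope array; \code{spectraCoefficients}
#' the complex Fourier coefficient array and \code{spectraFrequencies}
#' its frequency grid (Hz).
#'
#' @param x a streamsync container object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelTable", function(x) standardGeneric("channelTable"))
#' @rdname accessors
#' @export
setGeneric("sessionId", function(x) standardGeneric("sessionId"))
#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))
#' @rdname accessors
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))
#' @rdname accessors
#' @export
setGeneric("exclusionMask", function(x) standardGeneric("exclusionMask"))
#' @rdname accessors
#' @export
setGeneric("envelopeValues", function(x) standardGeneric("envelopeValues"))
#' @rdname accessors
#' @export
setGeneric("spectraCoefficients",
           function(x) standardGeneric("spectraCoefficients"))
#' @rdname accessors
#' @export
setGeneric("spectraFrequencies",
           function(x) standardGeneric("spectraFrequencies"))

#' @rdname accessors
setMethod("samples", "ContinuousRecording", function(x) x@samples)
#' @rdname accessors
setMethod("samplingRate", "ContinuousRecording", function(x) x@rate)
#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@rate)
#' @rdname accessors
setMethod("samplingRate", "ContinuousEnvelopes", function(x) x@rate)
#' @rdname accessors
setMethod("samplingRate", "EnvelopeSet", function(x) x@rate)
#' @rdname accessors
setMethod("channelTable", "ContinuousRecording", function(x) x@channels)
#' @rdname accessors
setMethod("channelTable", "EpochSet", function(x) x@channels)
#' @rdname accessors
setMethod("channelTable", "ContinuousEnvelopes", function(x) x@channels)
#' @rdname accessors
setMethod("channelTable", "EnvelopeSet", function(x) x@channels)
#' @rdname accessors
setMethod("channelTable", "TrialSpectra", function(x) x@channels)
#' @rdname accessors
setMethod("sessionId", "ContinuousRecording", function(x) x@sessionId)
#' @rdname accessors
setMethod("epochData", "EpochSet", function(x) x@data)
#' @rdname accessors
setMethod("conditionLabels", "EpochSet", function(x) x@condition)
#' @rdname accessors
setMethod("conditionLabels", "EnvelopeSet", function(x) x@condition)
#' @rdname accessors
setMethod("conditionLabels", "TrialSpectra", function(x) x@condition)
#' @rdname accessors
setMethod("exclusionMask", "EpochSet", function(x) x@excluded)
#' @rdname accessors
setMethod("exclusionMask", "EnvelopeSet", function(x) x@excluded)
#' @rdname accessors
setMethod("exclusionMask", "TrialSpectra", function(x) x@excluded)
#' @rdname accessors
setMethod("envelopeValues", "ContinuousEnvelopes", function(x) x@values)
#' @rdname accessors
setMethod("envelopeValues", "EnvelopeSet", function(x) x@values)
#' @rdname accessors
setMethod("spectraCoefficients", "TrialSpectra", function(x) x@coefficients)
#' @rdname accessors
setMethod("spectraFrequencies", "TrialSpectra", function(x) x@frequencies)
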