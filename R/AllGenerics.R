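## Generics for accessors and pipeline verbs.

#' @rdname TriaxSegment
#' @param x,object an object from this package
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @rdname TriaxSegment
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname TriaxSegment
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))

#' @rdname TriaxSegment
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname TremorSession
#' @export
setGeneric("segments", function(x) standardGeneric("segments"))

#' @rdname TremorSession
#' @export
setGeneric("dose", function(x) standardGeneric("dose"))

#' @rdname TremorSession
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname SummedSpectrogram
#' @export
setGeneric("windowTimes", function(x) standardGeneric("windowTimes"))

#' @rdname SummedSpectrogram
#' @export
setGeneric("freqBins", function(x) standardGeneric("freqBins"))

#' @rdname SummedSpectrogram
#' @export
setGeneric("spectralPower", function(x) standardGeneric("spectralPower"))

#' @rdname ArtifactMask
#' @export
setGeneric("keptWindows", function(x) standardGeneric("keptWindows"))

#' @rdname MPRSeries
#' @export
setGeneric("mprValues", function(x) standardGeneric("mprValues"))

#' @rdname MPRSeries
#' @export
setGeneric("normalizedMpr", function(x) standardGeneric("normalizedMpr"))

#' @rdname MPRSeries
#' @export
setGeneric("bands", function(x) standardGeneric("bands"))

#' @rdname spectral-ops
#' @export
setGeneric("summedSpectrogram",
           function(segment, ...) standardGeneric("summedSpectrogram"))

#' @rdname DriftFit
#' @export
setGeneric("driftSlope", function(x) standardGeneric("driftSlope"))

#' @rdname OnsetResult
#' @export
setGeneric("onsetTime", function(x) standardGeneric("onsetTime"))
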