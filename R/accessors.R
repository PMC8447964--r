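## Constructors, accessors and show() methods.

#' Construct a TriaxSegment
#'
#' @param channels samples x 3 numeric matrix of acceleration.
#' @param samplingRate samples per second.
#' @param startTime segment start, seconds relative to injection.
#' @param subjectId,segmentId identifiers.
#' @return A [TriaxSegment-class].
#' @examples
#' seg <- TriaxSegment(matrix(rnorm(300), ncol = 3), samplingRate = 50)
#' duration(seg)
#' @export
TriaxSegment <- function(channels, samplingRate, startTime = 0,
                         subjectId = "S", segmentId = "seg1") {
  channels <- as.matrix(channels)
  if (ncol(channels) != 3)
    stop("expected 3 acceleration channels, got ", ncol(channels))
  new("TriaxSegment", channels = channels, samplingRate = samplingRate,
      startTime = startTime, subjectId = subjectId, segmentId = segmentId)
}

#' Construct a TremorSession
#'
#' @param segments list of [TriaxSegment-class]; sorted by start time on
#'   construction.
#' @param subjectId subject identifier.
#' @param dose administered dose (mg/kg).
#' @param metadata free-form list.
#' @return A [TremorSession-class].
#' @export
TremorSession <- function(segments, subjectId = "S", dose = NA_real_,
                          metadata = list()) {
  st <- vapply(segments, function(s) s@startTime, numeric(1))
  segments <- segments[order(st)]
  new("TremorSession", subjectId = subjectId, dose = dose,
      injectionTime = 0, segments = segments, metadata = metadata)
}

#' Construct a BandDefinition
#'
#' @param tremorBand half-open (lo, hi) tremor band in Hz.
#' @param referenceBand half-open reference band in Hz (default 17-21 Hz).
#' @param secondaryBand optional second tremor band.
#' @return A [BandDefinition-class].
#' @examples
#' BandDefinition()                     # 10-14 Hz vs 17-21 Hz
#' BandDefinition(c(12, 16))
#' @export
BandDefinition <- function(tremorBand = c(10, 14),
                           referenceBand = c(17, 21),
                           secondaryBand = numeric(0)) {
  new("BandDefinition", tremorBand = as.numeric(tremorBand),
      referenceBand = as.numeric(referenceBand),
      secondaryBand = as.numeric(secondaryBand))
}

#' @rdname TriaxSegment
#' @export
setMethod("channels", "TriaxSegment", function(x) x@channels)

#' @rdname TriaxSegment
#' @export
setMethod("samplingRate", "TriaxSegment", function(x) x@samplingRate)

#' @rdname TriaxSegment
#' @export
setMethod("startTime", "TriaxSegment", function(x) x@startTime)

#' @rdname TriaxSegment
#' @export
setMethod("duration", "TriaxSegment",
          function(x) nrow(x@channels) / x@samplingRate)

#' @rdname TremorSession
#' @export
setMethod("segments", "TremorSession", function(x) x@segments)

#' @rdname TremorSession
#' @export
setMethod("dose", "TremorSession", function(x) x@dose)

#' @rdname TremorSession
#' @export
setMethod("subjectId", "TremorSession", function(x) x@subjectId)

#' @rdname SummedSpectrogram
#' @export
setMethod("windowTimes", "SummedSpectrogram", function(x) x@windowTimes)

#' @rdname SummedSpectrogram
#' @export
setMethod("freqBins", "SummedSpectrogram", function(x) x@freqBins)

#' @rdname SummedSpectrogram
#' @export
setMethod("spectralPower", "SummedSpectrogram", function(x) x@power)

#' @rdname ArtifactMask
#' @export
setMethod("keptWindows", "ArtifactMask", function(x) x@keep)

#' @rdname ArtifactMask
#' @export
setMethod("windowTimes", "ArtifactMask", function(x) x@windowTimes)

#' @rdname MPRSeries
#' @export
setMethod("windowTimes", "MPRSeries", function(x) x@windowTimes)

#' @rdname MPRSeries
#' @export
setMethod("mprValues", "MPRSeries", function(x) x@mpr)

#' @rdname MPRSeries
#' @export
setMethod("normalizedMpr", "MPRSeries", function(x) x@normalizedMpr)

#' @rdname MPRSeries
#' @export
setMethod("bands", "MPRSeries", function(x) x@bands)

#' @rdname DriftFit
#' @export
setMethod("driftSlope", "DriftFit", function(x) x@slope)

#' @rdname OnsetResult
#' @export
setMethod("onsetTime", "OnsetResult", function(x) x@onsetTime)

setMethod("show", "TriaxSegment", function(object) {
  cat(sprintf("TriaxSegment %s [%s]: %.1f s at %g samples/s, start %.1f s\n",
              object@segmentId, object@subjectId, duration(object),
              object@samplingRate, object@startTime))
})

setMethod("show", "TremorSession", function(object) {
  st <- vapply(object@segments, startTime, numeric(1))
  cat(sprintf("TremorSession: subject %s, dose %s mg/kg, %d segments\n",
              object@subjectId, format(object@dose), length(object@segments)))
  if (length(st))
    cat(sprintf("  spanning %.1f to %.1f min relative to injection\n",
                min(st) / 60,
                max(st + vapply(object@segments, duration, numeric(1))) / 60))
})

setMethod("show", "SummedSpectrogram", function(object) {
  cat(sprintf("SummedSpectrogram %s: %d windows x %d bins (0-%.1f Hz)\n",
              object@segmentId, nrow(object@power), ncol(object@power),
              max(object@freqBins)))
})

setMethod("show", "ArtifactMask", function(object) {
  cat(sprintf("ArtifactMask: %d/%d windows kept (median %.3g, MAD %.3g)\n",
              sum(object@keep), length(object@keep),
              object@sessionMedianPower, object@sessionMadPower))
})

setMethod("show", "PSDEstimate", function(object) {
  cat(sprintf("PSDEstimate %s: nfft %d, df %.4f Hz, midpoint %.1f min\n",
              object@segmentId, object@nfft,
              object@samplingRate / object@nfft, object@midpointTime / 60))
})

setMethod("show", "BandDefinition", function(object) {
  cat(sprintf("BandDefinition: tremor [%g, %g) Hz vs reference [%g, %g) Hz\n",
              object@tremorBand[1], object@tremorBand[2],
              object@referenceBand[1], object@referenceBand[2]))
  if (length(object@secondaryBand))
    cat(sprintf("  secondary band [%g, %g) Hz\n",
                object@secondaryBand[1], object@secondaryBand[2]))
})

setMethod("show", "MPRSeries", function(object) {
  cat(sprintf("MPRSeries: %d windows, median MPR %.3g%s\n",
              length(object@mpr), stats::median(object@mpr),
              if (is.na(object@baselineMedian)) " (not normalized)"
              else sprintf(", baseline median %.3g", object@baselineMedian)))
})

setMethod("show", "DriftFit", function(object) {
  cat(sprintf("DriftFit: slope %.4f Hz/min (95%% CI %.4f, %.4f), n = %d\n",
              object@slope, object@slopeCi[1], object@slopeCi[2],
              object@nPoints))
})

setMethod("show", "OnsetResult", function(object) {
  if (is.na(object@onsetTime))
    cat("OnsetResult: no tremor onset detected\n")
  else
    cat(sprintf("OnsetResult: onset %.1f min post-injection (segment %s)\n",
                object@onsetTime, object@onsetSegmentId))
})

setMethod("show", "DoseResponse", function(object) {
  cat(sprintf("DoseResponse [%s]: r = %.4f, p = %.4f (n = %d dose levels)\n",
              object@metric, object@r, object@pValue, object@n))
})
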