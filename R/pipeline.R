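## End-to-end orchestration: preprocess -> spectrogram -> artifact
## rejection -> MPR/baseline -> per-segment tests -> onset -> PSD/peak ->
## drift fit, with every parameter echoed into the report for provenance.

#' Pipeline configuration
#'
#' All defaults are the analysis parameters of the study design: 6th-order
#' causal Butterworth high-pass at 1 Hz; 1-s Hamming spectrogram windows
#' with no overlap; artifact rejection at 3 unscaled MADs over the session;
#' Welch PSDs with 4-s Hamming windows, 50% overlap and next-power-of-two
#' FFT length; tremor band 10-14 Hz against the 17-21 Hz reference band;
#' 900-s baseline cutoff; FDR 1e-4; 15-min drift cutoff; 1000 bootstrap
#' resamples for segment-median confidence intervals.
#'
#' @param ... named overrides of the defaults listed above.
#' @return A named list of class `PipelineConfig`.
#' @examples
#' cfg <- pipelineConfig(referenceBand = c(16, 20))
#' cfg$referenceBand
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    highpass = TRUE, filterOrder = 6, filterCutoff = 1, zeroPhase = FALSE,
    spectrogramWindowSec = 1,
    artifactNMad = 3,
    welchWindowSec = 4, welchOverlap = 0.5,
    bandSelect = "fixed",               # or "auto"
    tremorBand = c(10, 14), referenceBand = c(17, 21),
    bandSearchRange = c(8, 16), bandHalfWidth = 2,
    baselineCutoff = 900,
    fdr = 1e-4,
    driftCutoffMin = 15, driftNMadResid = 3,
    ciLevel = 0.95, nBoot = 1000, bootSeed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("pipelineConfig: unknown option(s) ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "PipelineConfig")
}

#' Run the full tremor-quantification pipeline on one session
#'
#' Executes, in order: per-segment conditioning (linear detrend then 1 Hz
#' high-pass), summed 1-s spectrograms, session-level MAD artifact
#' rejection, Welch PSDs of the artifact-free data with tremor-band peak
#' tracking, tremor/reference band definition (fixed or data-driven), the
#' baseline-normalized motion power ratio, per-segment signed-rank tests
#' with Benjamini-Hochberg control, tremor-onset extraction, and the linear
#' peak-frequency drift regression. With a fixed configuration and input
#' the report is deterministic (bootstrap intervals are seeded from
#' `config$bootSeed`).
#'
#' @param session a [TremorSession-class] of raw segments.
#' @param config a [pipelineConfig()] list.
#' @return A list of class `tremorReport` with elements `config`, `counts`
#'   (windows before/after artifact rejection), `bands`, `baseline`,
#'   `segmentStats`, `onset` (an [OnsetResult-class]), `peaks` (per-segment
#'   peak-frequency table) and `drift` (a [DriftFit-class] or NULL when too
#'   few points survive).
#' @export
runPipeline <- function(session, config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "': ", conditionMessage(e),
           call. = FALSE))
  }
  conditioned <- stage("preprocess", preprocessSession(
    session, highpass = config$highpass, cutoff = config$filterCutoff,
    order = config$filterOrder, zeroPhase = config$zeroPhase))
  specs <- stage("spectrogram", sessionSpectrograms(conditioned))
  mask <- stage("artifact-rejection",
                rejectArtifacts(specs, nMad = config$artifactNMad))
  psds <- stage("welch-psd", sessionPsds(
    conditioned, mask, windowSec = config$welchWindowSec,
    overlap = config$welchOverlap))
  bands <- stage("band-definition", {
    if (identical(config$bandSelect, "auto"))
      selectTremorBand(psds, searchRange = config$bandSearchRange,
                       halfWidth = config$bandHalfWidth,
                       baselineCutoff = config$baselineCutoff)
    else BandDefinition(config$tremorBand, config$referenceBand)
  })
  mpr <- stage("mpr", {
    m <- mprSeries(specs, mask, bands)
    normalizeMpr(m, baselineMedian(m, baselineCutoff = config$baselineCutoff))
  })
  segStats <- stage("segment-stats", segmentStats(
    mpr, fdr = config$fdr, level = config$ciLevel, nBoot = config$nBoot,
    seed = config$bootSeed))
  onset <- stage("onset", detectOnset(segStats,
                                      baselineCutoff = config$baselineCutoff))
  peaks <- stage("peak-tracking", {
    if (!length(psds)) NULL
    else do.call(rbind, lapply(psds, function(p) data.frame(
      segmentId = p@segmentId, midpointMin = p@midpointTime / 60,
      peakFreq = peakFrequency(p, band = bands@tremorBand),
      binWidth = p@samplingRate / p@nfft, stringsAsFactors = FALSE)))
  })
  drift <- stage("drift-fit", {
    ok <- !is.null(peaks) &&
      sum(peaks$midpointMin > config$driftCutoffMin) >= 3
    if (!ok) NULL
    else tryCatch(
      fitDrift(peaks$midpointMin, peaks$peakFreq,
               cutoffMin = config$driftCutoffMin, band = bands@tremorBand,
               edgeTol = peaks$binWidth[1],
               nMadResid = config$driftNMadResid, level = config$ciLevel),
      error = function(e) NULL)  # too few usable points: no drift estimate
  })
  structure(list(
    subjectId = session@subjectId, dose = session@dose, config = config,
    counts = list(nSegments = length(segments(session)),
                  nWindows = length(mask@keep), nKept = sum(mask@keep)),
    bands = bands, baseline = baselineMedian(
      mpr, baselineCutoff = config$baselineCutoff),
    mpr = mpr, segmentStats = segStats, onset = onset, peaks = peaks,
    drift = drift), class = "tremorReport")
}

#' @export
print.tremorReport <- function(x, ...) {
  cat(sprintf("tremorquant report: subject %s, dose %s mg/kg\n",
              x$subjectId, format(x$dose)))
  cat(sprintf("  %d segments, %d/%d windows kept after artifact rejection\n",
              x$counts$nSegments, x$counts$nKept, x$counts$nWindows))
  show(x$bands)
  show(x$onset)
  if (!is.null(x$drift)) show(x$drift)
  invisible(x)
}
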