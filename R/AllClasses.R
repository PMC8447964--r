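## S4 classes for the tremor-quantification pipeline.
##
## Raw data containers (TriaxSegment, TremorSession) hold episodic triaxial
## wrist accelerometry relative to an injection event; derived containers
## (SummedSpectrogram, ArtifactMask, PSDEstimate, MPRSeries) hold the spectral
## products; profile/plan classes parameterize the synthetic-session
## generator. All times are seconds relative to injection (negative =
## pre-injection) except where a function documents minutes.

#' TremorProfile: parameters of a simulated tremor oscillation
#'
#' Describes the tremor component injected by [simulateSession()]: a single
#' amplitude-modulated oscillation whose instantaneous frequency drifts
#' linearly downward after onset, gated on and off in 1-second epochs to
#' emulate the intermittency seen in pharmacological tremor.
#'
#' @slot onsetTime seconds post-injection at which tremor becomes possible
#'   (wash-in); must be >= 0.
#' @slot peakFreqAtOnset instantaneous oscillation frequency (Hz) at onset.
#' @slot driftSlope linear frequency drift in Hz per minute (typically <= 0).
#' @slot amplitude oscillation amplitude in the same arbitrary acceleration
#'   units as the noise model; 0 disables the tremor entirely.
#' @slot intermittencyDuty fraction in [0, 1] of post-onset 1-s epochs in
#'   which the tremor is active.
#' @slot envelopeTimescale raised-cosine on/off ramp duration in seconds
#'   applied at epoch gating transitions.
#' @export
setClass("TremorProfile",
  representation(
    onsetTime = "numeric",
    peakFreqAtOnset = "numeric",
    driftSlope = "numeric",
    amplitude = "numeric",
    intermittencyDuty = "numeric",
    envelopeTimescale = "numeric"
  )
)

setValidity("TremorProfile", function(object) {
  msg <- character()
  if (length(object@onsetTime) != 1 || object@onsetTime < 0)
    msg <- c(msg, "onsetTime must be a single value >= 0")
  if (object@peakFreqAtOnset <= 0)
    msg <- c(msg, "peakFreqAtOnset must be > 0")
  if (object@intermittencyDuty < 0 || object@intermittencyDuty > 1)
    msg <- c(msg, "intermittencyDuty must lie in [0, 1]")
  if (object@amplitude < 0)
    msg <- c(msg, "amplitude must be >= 0")
  if (object@envelopeTimescale < 0 || object@envelopeTimescale >= 1)
    msg <- c(msg, "envelopeTimescale must lie in [0, 1) seconds")
  if (length(msg)) msg else TRUE
})

#' NoiseProfile: background motion and artifact model
#'
#' Parameterizes the non-tremor content of a simulated session: broadband
#' sensor/motion noise, a low-frequency (< 5 Hz) postural-drift component,
#' and brief high-amplitude broadband transients emulating sudden jerky
#' movements.
#'
#' @slot broadbandSd standard deviation of the white background noise
#'   (arbitrary acceleration units).
#' @slot lowFreqMotionSd standard deviation of the < 5 Hz postural motion
#'   component.
#' @slot artifactRate expected jerk-artifact count per minute.
#' @slot artifactAmplitudeFactor artifact amplitude as a multiple of
#'   `broadbandSd`.
#' @slot artifactDuration artifact duration in seconds; must be < 1 so a
#'   transient touches at most two adjacent 1-s analysis windows.
#' @export
setClass("NoiseProfile",
  representation(
    broadbandSd = "numeric",
    lowFreqMotionSd = "numeric",
    artifactRate = "numeric",
    artifactAmplitudeFactor = "numeric",
    artifactDuration = "numeric"
  )
)

setValidity("NoiseProfile", function(object) {
  msg <- character()
  vals <- c(object@broadbandSd, object@lowFreqMotionSd, object@artifactRate,
            object@artifactAmplitudeFactor, object@artifactDuration)
  if (any(vals < 0))
    msg <- c(msg, "all noise parameters must be non-negative")
  if (object@artifactDuration >= 1)
    msg <- c(msg, "artifactDuration must be < 1 s")
  if (length(msg)) msg else TRUE
})

#' SessionPlan: recording schedule for a simulated session
#'
#' @slot samplingRate samples per second (the study rates were 617, 500 and
#'   1017.3 samples/s).
#' @slot schedule data.frame with columns `start` and `duration` (seconds),
#'   one row per episodic recording segment; sorted, non-overlapping.
#' @slot seed integer RNG seed; identical plans produce bit-identical
#'   sessions.
#' @export
setClass("SessionPlan",
  representation(
    samplingRate = "numeric",
    schedule = "data.frame",
    seed = "integer"
  )
)

setValidity("SessionPlan", function(object) {
  msg <- character()
  sch <- object@schedule
  if (!all(c("start", "duration") %in% names(sch)))
    msg <- c(msg, "schedule needs columns 'start' and 'duration'")
  else {
    if (nrow(sch) < 1) msg <- c(msg, "schedule must have at least one segment")
    if (any(sch$duration <= 0)) msg <- c(msg, "durations must be > 0")
    if (is.unsorted(sch$start, strictly = TRUE))
      msg <- c(msg, "segments must be sorted by start time")
    if (nrow(sch) > 1 &&
        any(sch$start[-1] < (sch$start + sch$duration)[-nrow(sch)]))
      msg <- c(msg, "segments must not overlap")
    if (!any(sch$start + sch$duration <= 900))
      msg <- c(msg, "at least one segment must lie entirely in the baseline period (end <= 900 s)")
  }
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' TaskPlan: dose-response design for simulated reach-task sessions
#'
#' @slot doses mg/kg levels, 0 denoting drug-naive (vehicle) sessions.
#' @slot engagementSlope change in expected attempted-reach count per mg/kg.
#' @slot prematureSlope change in expected premature fraction per mg/kg.
#' @slot baselineReaches expected attempted reaches at dose 0.
#' @slot baselinePrematureFrac expected premature fraction at dose 0.
#' @slot sessionMinutes allotted task minutes on dose days.
#' @slot naiveMinutes allotted task minutes on drug-naive days.
#' @slot nSessionsPerDose sessions simulated at each non-zero dose.
#' @slot nNaiveSessions drug-naive sessions simulated (pooled downstream).
#' @slot seed integer RNG seed.
#' @export
setClass("TaskPlan",
  representation(
    doses = "numeric",
    engagementSlope = "numeric",
    prematureSlope = "numeric",
    baselineReaches = "numeric",
    baselinePrematureFrac = "numeric",
    sessionMinutes = "numeric",
    naiveMinutes = "numeric",
    nSessionsPerDose = "integer",
    nNaiveSessions = "integer",
    seed = "integer"
  )
)

setValidity("TaskPlan", function(object) {
  msg <- character()
  if (length(object@doses) == 0)
    msg <- c(msg, "dose list must not be empty")
  if (object@baselineReaches < 0)
    msg <- c(msg, "baselineReaches must be >= 0")
  if (object@baselinePrematureFrac < 0 || object@baselinePrematureFrac > 1)
    msg <- c(msg, "baselinePrematureFrac must lie in [0, 1]")
  if (object@nSessionsPerDose < 1 || object@nNaiveSessions < 1)
    msg <- c(msg, "session counts must be >= 1")
  if (length(msg)) msg else TRUE
})

#' TriaxSegment: one episodic triaxial accelerometry recording
#'
#' @slot channels numeric matrix, samples x 3 axes, uniformly sampled
#'   acceleration in arbitrary units.
#' @slot samplingRate samples per second.
#' @slot startTime segment start in seconds relative to injection
#'   (negative = pre-injection).
#' @slot subjectId subject identifier.
#' @slot segmentId unique segment identifier within the session.
#' @export
setClass("TriaxSegment",
  representation(
    channels = "matrix",
    samplingRate = "numeric",
    startTime = "numeric",
    subjectId = "character",
    segmentId = "character"
  )
)

setValidity("TriaxSegment", function(object) {
  msg <- character()
  if (ncol(object@channels) != 3)
    msg <- c(msg, "expected 3 acceleration channels")
  if (!is.numeric(object@channels))
    msg <- c(msg, "channels must be numeric")
  if (object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be > 0")
  if (length(msg)) msg else TRUE
})

#' TremorSession: a dosing session's episodic recordings
#'
#' @slot subjectId subject identifier.
#' @slot dose administered dose in mg/kg.
#' @slot injectionTime injection reference time (always 0; all segment
#'   times are stored relative to it).
#' @slot segments list of [TriaxSegment-class] sorted by start time,
#'   non-overlapping.
#' @slot metadata free-form list; [simulateSession()] stores the ground
#'   truth (programmed onset, artifact energies) here.
#' @export
setClass("TremorSession",
  representation(
    subjectId = "character",
    dose = "numeric",
    injectionTime = "numeric",
    segments = "list",
    metadata = "list"
  )
)

setValidity("TremorSession", function(object) {
  msg <- character()
  if (!all(vapply(object@segments, is, logical(1), "TriaxSegment")))
    msg <- c(msg, "segments must all be TriaxSegment objects")
  else if (length(object@segments) > 1) {
    st <- vapply(object@segments, function(s) s@startTime, numeric(1))
    en <- st + vapply(object@segments, duration, numeric(1))
    if (is.unsorted(st, strictly = TRUE))
      msg <- c(msg, "segments must be sorted by startTime")
    else if (any(st[-1] < en[-length(en)]))
      msg <- c(msg, "segments must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' SummedSpectrogram: per-second power summed over the three axes
#'
#' Magnitude-squared short-time Fourier transform over non-overlapping 1-s
#' Hamming windows, summed bin-wise across the three acceleration axes.
#'
#' @slot windowTimes window midpoints, seconds relative to injection.
#' @slot freqBins one-sided DFT frequency grid of a 1-s window (about 1 Hz
#'   spacing).
#' @slot power non-negative matrix, windows x bins.
#' @slot segmentId source segment identifier.
#' @export
setClass("SummedSpectrogram",
  representation(
    windowTimes = "numeric",
    freqBins = "numeric",
    power = "matrix",
    segmentId = "character"
  )
)

setValidity("SummedSpectrogram", function(object) {
  msg <- character()
  if (nrow(object@power) != length(object@windowTimes))
    msg <- c(msg, "power must have one row per window")
  if (ncol(object@power) != length(object@freqBins))
    msg <- c(msg, "power must have one column per frequency bin")
  if (any(object@power < 0))
    msg <- c(msg, "power must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ArtifactMask: session-level movement-artifact rejection
#'
#' Flags 1-s windows whose summed spectral power falls outside 3 (unscaled)
#' median absolute deviations of the median over all windows of the session.
#'
#' @slot keep logical per window, session-wide.
#' @slot windowTimes window midpoints (seconds).
#' @slot segmentIds source segment of each window.
#' @slot sessionMedianPower median of summed window power over the session.
#' @slot sessionMadPower unscaled MAD of summed window power.
#' @export
setClass("ArtifactMask",
  representation(
    keep = "logical",
    windowTimes = "numeric",
    segmentIds = "character",
    sessionMedianPower = "numeric",
    sessionMadPower = "numeric"
  )
)

#' PSDEstimate: Welch power spectral density of a cleaned segment
#'
#' @slot freqs frequency grid, spacing exactly samplingRate / nfft.
#' @slot power one-sided spectral density summed over the three axes.
#' @slot nfft FFT length (next power of two >= the 4-s window, minimum 256).
#' @slot segmentId source segment identifier.
#' @slot midpointTime segment midpoint, seconds relative to injection.
#' @slot samplingRate samples per second.
#' @export
setClass("PSDEstimate",
  representation(
    freqs = "numeric",
    power = "numeric",
    nfft = "integer",
    segmentId = "character",
    midpointTime = "numeric",
    samplingRate = "numeric"
  )
)

#' BandDefinition: tremor and reference frequency bands
#'
#' Bands are half-open intervals [lo, hi) on the spectrogram frequency grid.
#' The reference band defaults to 17-21 Hz (non-tremor movement power); the
#' tremor band defaults to the 10-14 Hz range in which primate harmaline
#' tremor concentrates.
#'
#' @slot tremorBand numeric length 2, half-open tremor band (Hz).
#' @slot referenceBand numeric length 2, half-open reference band (Hz).
#' @slot secondaryBand optional second tremor band (length 0 when absent),
#'   for sessions with a second oscillatory mode.
#' @export
setClass("BandDefinition",
  representation(
    tremorBand = "numeric",
    referenceBand = "numeric",
    secondaryBand = "numeric"
  )
)

setValidity("BandDefinition", function(object) {
  msg <- character()
  ok2 <- function(b) length(b) == 2 && b[1] < b[2]
  if (!ok2(object@tremorBand)) msg <- c(msg, "tremorBand must be (lo, hi) with lo < hi")
  if (!ok2(object@referenceBand)) msg <- c(msg, "referenceBand must be (lo, hi) with lo < hi")
  if (ok2(object@tremorBand) && ok2(object@referenceBand)) {
    if (object@tremorBand[2] > object@referenceBand[1] &&
        object@referenceBand[2] > object@tremorBand[1])
      msg <- c(msg, "tremor and reference bands must not overlap")
  }
  if (length(object@secondaryBand) %in% c(0L, 2L) == FALSE)
    msg <- c(msg, "secondaryBand must be empty or (lo, hi)")
  if (length(msg)) msg else TRUE
})

#' MPRSeries: per-window motion power ratio
#'
#' Motion power ratio (MPR) is tremor-band power divided by reference-band
#' power, computed per artifact-free 1-s spectrogram window. Once a baseline
#' median is known, `normalizedMpr = mpr / baselineMedian`.
#'
#' @slot windowTimes window midpoints (seconds relative to injection).
#' @slot segmentIds source segment of each window.
#' @slot mpr raw motion power ratio per window.
#' @slot normalizedMpr baseline-normalized MPR (NA until normalized).
#' @slot bands the [BandDefinition-class] used.
#' @slot baselineMedian normalization divisor (NA until normalized).
#' @export
setClass("MPRSeries",
  representation(
    windowTimes = "numeric",
    segmentIds = "character",
    mpr = "numeric",
    normalizedMpr = "numeric",
    bands = "BandDefinition",
    baselineMedian = "numeric"
  )
)

setValidity("MPRSeries", function(object) {
  n <- length(object@windowTimes)
  if (length(object@segmentIds) != n || length(object@mpr) != n ||
      length(object@normalizedMpr) != n)
    "windowTimes, segmentIds, mpr and normalizedMpr must have equal length"
  else TRUE
})

#' DriftFit: linear peak-frequency drift regression
#'
#' @slot slope fitted drift in Hz per minute.
#' @slot intercept fitted intercept (Hz at time 0).
#' @slot slopeCi 95% confidence interval on the slope (t-based OLS).
#' @slot nPoints points used after cutoff and outlier exclusion.
#' @slot excluded indices (into the post-cutoff points) dropped as band-edge
#'   saturated or residual outliers.
#' @export
setClass("DriftFit",
  representation(
    slope = "numeric",
    intercept = "numeric",
    slopeCi = "numeric",
    nPoints = "integer",
    excluded = "integer"
  )
)

#' OnsetResult: detected tremor onset
#'
#' @slot onsetTime onset in minutes post-injection (NA when no onset).
#' @slot onsetSegmentId identifier of the earliest significantly elevated
#'   post-baseline segment (NA when none).
#' @export
setClass("OnsetResult",
  representation(
    onsetTime = "numeric",
    onsetSegmentId = "character"
  )
)

#' DoseResponse: Pearson dose-response summary
#'
#' @slot metric name of the summarized behavioral metric.
#' @slot doses dose levels entering the correlation.
#' @slot means per-dose metric means.
#' @slot r Pearson correlation between dose and metric mean.
#' @slot pValue two-sided p from the t transform with n - 2 df.
#' @slot n number of dose levels.
#' @export
setClass("DoseResponse",
  representation(
    metric = "character",
    doses = "numeric",
    means = "numeric",
    r = "numeric",
    pValue = "numeric",
    n = "integer"
  )
)
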