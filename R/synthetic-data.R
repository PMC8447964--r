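## Seeded synthetic-session generator. Emulates the statistical structure
## the analysis assumes in primate harmaline sessions: background motion
## noise, a 10-14 Hz tremor oscillation appearing 20-30 min post-injection
## with epoch-wise intermittency and a slow linear downward frequency
## drift, and brief broadband jerk artifacts. Identical seeds give
## bit-identical sessions.

#' @rdname TremorProfile
#' @param onsetTime,peakFreqAtOnset,driftSlope,amplitude,intermittencyDuty,envelopeTimescale
#'   see the class slots. Defaults encode the study conditions: onset
#'   25 min post-injection (mid wash-in range), 12 Hz at onset,
#'   -0.0165 Hz/min drift (mid-range of the fitted subject slopes), duty
#'   0.7. The default amplitude of 0.35 broadband-noise SDs makes the
#'   tremor narrowband-dominant but whole-spectrum-modest: it multiplies
#'   tremor-band power severalfold while adding only a few percent to the
#'   total motion power of a window, which is how tremor manifests against
#'   whole-body movement in the recordings this emulates (and why real
#'   tremor is not swept up by the session-level artifact rule).
#' @return A [TremorProfile-class].
#' @export
TremorProfile <- function(onsetTime = 1500, peakFreqAtOnset = 12,
                          driftSlope = -0.0165, amplitude = 0.35,
                          intermittencyDuty = 0.7,
                          envelopeTimescale = 0.1) {
  new("TremorProfile", onsetTime = onsetTime,
      peakFreqAtOnset = peakFreqAtOnset, driftSlope = driftSlope,
      amplitude = amplitude, intermittencyDuty = intermittencyDuty,
      envelopeTimescale = envelopeTimescale)
}

#' @rdname NoiseProfile
#' @param broadbandSd,lowFreqMotionSd,artifactRate,artifactAmplitudeFactor,artifactDuration
#'   see the class slots.
#' @return A [NoiseProfile-class].
#' @export
NoiseProfile <- function(broadbandSd = 1, lowFreqMotionSd = 0.5,
                         artifactRate = 0.5, artifactAmplitudeFactor = 10,
                         artifactDuration = 0.3) {
  new("NoiseProfile", broadbandSd = broadbandSd,
      lowFreqMotionSd = lowFreqMotionSd, artifactRate = artifactRate,
      artifactAmplitudeFactor = artifactAmplitudeFactor,
      artifactDuration = artifactDuration)
}

#' Default episodic recording schedule
#'
#' Four 2-minute baseline segments (two pre-injection, two inside the
#' 15-minute wash-in window) followed by contiguous 2-minute segments from
#' 16 to 40 minutes post-injection, emulating a continuously streamed
#' session cut at the 2-minute maximum segment length.
#'
#' @param postEnd end of the post-injection coverage, seconds.
#' @param segLen segment duration in seconds.
#' @return data.frame with `start` and `duration` columns.
#' @export
defaultSchedule <- function(postEnd = 2400, segLen = 120) {
  baseline <- c(-480, -240, 60, 420)
  post <- seq(960, postEnd - segLen, by = segLen)
  data.frame(start = c(baseline, post),
             duration = segLen)
}

#' @rdname SessionPlan
#' @param samplingRate,schedule,seed see the class slots.
#' @return A [SessionPlan-class].
#' @export
SessionPlan <- function(samplingRate = 500, schedule = defaultSchedule(),
                        seed = 1L) {
  new("SessionPlan", samplingRate = samplingRate, schedule = schedule,
      seed = as.integer(seed))
}

#' @rdname TaskPlan
#' @param doses,engagementSlope,prematureSlope,baselineReaches,baselinePrematureFrac,sessionMinutes,naiveMinutes,nSessionsPerDose,nNaiveSessions,seed
#'   see the class slots. Defaults encode the task study: doses 0 (vehicle)
#'   and 2-8 mg/kg, 30-minute dose sessions, 15-minute naive sessions,
#'   engagement falling and impulsivity rising with dose.
#' @return A [TaskPlan-class].
#' @export
TaskPlan <- function(doses = c(0, 2, 4, 6, 8), engagementSlope = -10,
                     prematureSlope = 0.03, baselineReaches = 100,
                     baselinePrematureFrac = 0.05, sessionMinutes = 30,
                     naiveMinutes = 15, nSessionsPerDose = 2L,
                     nNaiveSessions = 8L, seed = 1L) {
  new("TaskPlan", doses = doses, engagementSlope = engagementSlope,
      prematureSlope = prematureSlope, baselineReaches = baselineReaches,
      baselinePrematureFrac = baselinePrematureFrac,
      sessionMinutes = sessionMinutes, naiveMinutes = naiveMinutes,
      nSessionsPerDose = as.integer(nSessionsPerDose),
      nNaiveSessions = as.integer(nNaiveSessions), seed = as.integer(seed))
}

## fixed projection of the (one-dimensional) tremor axis onto the three
## accelerometer axes; the analysis sums axes, so only configurability
## matters, not the particular direction
tremorAxisWeights <- function(w = c(0.7, 0.5, 0.5)) {
  w / sqrt(sum(w^2))
}

## raised-cosine smoothing of a 0/1 epoch gate, ramp length `ramp` seconds
smoothGate <- function(gate, fs, ramp) {
  k <- max(1L, round(ramp * fs))
  if (k == 1L || length(gate) <= 1L) return(gate)
  win <- (1 - cos(2 * pi * seq_len(k) / (k + 1))) / 2
  win <- win / sum(win)
  padded <- c(rep(gate[1], k), gate, rep(gate[length(gate)], k))
  sm <- stats::filter(padded, win, sides = 2)
  as.numeric(sm[(k + 1):(k + length(gate))])
}

#' Simulate one accelerometry dosing session
#'
#' Generates the episodic triaxial segments of a dosing session. Each
#' segment is the sum of:
#' \itemize{
#'   \item white broadband noise per axis;
#'   \item a low-frequency (< 5 Hz) filtered-noise postural component;
#'   \item after `onsetTime`, a tremor chirp whose instantaneous frequency
#'     is `peakFreqAtOnset + driftSlope/60 * (t - onsetTime)` (phase is the
#'     integral of the drifting frequency, so there are no phase
#'     discontinuities), gated on 1-s epochs by a seeded Bernoulli(duty)
#'     draw smoothed with a raised-cosine ramp, and projected onto the
#'     three axes with fixed unit-vector weights;
#'   \item brief broadband jerk artifacts (half-sine-enveloped noise
#'     bursts) at the configured rate.
#' }
#' The ground truth (programmed onset, drift, and the artifact energy
#' deposited into each 1-s analysis window) is stored in the session
#' metadata under `$truth`. Identical profiles and seed give bit-identical
#' sessions.
#'
#' @param tremor a [TremorProfile-class].
#' @param noise a [NoiseProfile-class].
#' @param plan a [SessionPlan-class] (schedule, sampling rate, seed).
#' @param subjectId,dose session metadata.
#' @return A [TremorSession-class].
#' @examples
#' plan <- SessionPlan(schedule = data.frame(start = c(-120, 960),
#'                                           duration = 60), seed = 7)
#' ses <- simulateSession(TremorProfile(), NoiseProfile(), plan)
#' ses
#' @export
simulateSession <- function(tremor = TremorProfile(),
                            noise = NoiseProfile(),
                            plan = SessionPlan(),
                            subjectId = "sim", dose = 10) {
  methods::validObject(tremor)
  methods::validObject(noise)
  methods::validObject(plan)
  fs <- plan@samplingRate
  wAxes <- tremorAxisWeights()
  slopePerSec <- tremor@driftSlope / 60
  ## frequency must stay positive over the whole schedule
  tMax <- max(plan@schedule$start + plan@schedule$duration)
  if (tMax > tremor@onsetTime && tremor@amplitude > 0 &&
      tremor@peakFreqAtOnset + slopePerSec * (tMax - tremor@onsetTime) <= 0)
    stop("simulateSession: drift drives the tremor frequency below 0 Hz ",
         "within the session")
  artifactRows <- list()
  segs <- withSeed(plan@seed, {
    lapply(seq_len(nrow(plan@schedule)), function(i) {
      start <- plan@schedule$start[i]
      dur <- plan@schedule$duration[i]
      n <- round(dur * fs)
      t <- start + (0:(n - 1)) / fs
      segId <- sprintf("seg%02d", i)
      ## background: white + low-frequency postural motion
      ch <- matrix(stats::rnorm(n * 3, sd = noise@broadbandSd), n, 3)
      if (noise@lowFreqMotionSd > 0) {
        lp <- signal::butter(4, min(5 / (fs / 2), 0.99), type = "low")
        for (ax in 1:3) {
          lf <- as.numeric(signal::filter(lp, stats::rnorm(n)))
          s <- stats::sd(lf)
          if (s > 0) ch[, ax] <- ch[, ax] + lf * (noise@lowFreqMotionSd / s)
        }
      }
      ## tremor chirp with epoch-gated intermittency
      if (tremor@amplitude > 0 && any(t >= tremor@onsetTime)) {
        nEpochs <- ceiling(dur)
        gates <- as.numeric(stats::runif(nEpochs) < tremor@intermittencyDuty)
        epoch <- pmin(floor(t - start), nEpochs - 1) + 1
        env <- gates[epoch] * (t >= tremor@onsetTime)
        env <- smoothGate(env, fs, tremor@envelopeTimescale)
        rel <- pmax(t - tremor@onsetTime, 0)
        phase <- 2 * pi * (tremor@peakFreqAtOnset * rel +
                             0.5 * slopePerSec * rel^2)
        sig <- tremor@amplitude * env * sin(phase)
        ch <- ch + outer(sig, wAxes)
      }
      ## brief broadband jerk artifacts
      nArt <- stats::rpois(1, noise@artifactRate * dur / 60)
      if (nArt > 0 && noise@artifactAmplitudeFactor > 0) {
        n1 <- round(fs)                  # 1-s analysis window length
        nw <- n %/% n1
        lenA <- max(1L, round(noise@artifactDuration * fs))
        wham2 <- signal::hamming(n1)^2
        for (a in seq_len(nArt)) {
          s0 <- 1 + floor(stats::runif(1) * (n - lenA))
          idx <- s0:(s0 + lenA - 1)
          envA <- sin(pi * seq_len(lenA) / (lenA + 1))
          burst <- matrix(stats::rnorm(lenA * 3,
                                       sd = noise@artifactAmplitudeFactor *
                                         noise@broadbandSd), lenA, 3) * envA
          ch[idx, ] <- ch[idx, ] + burst
          ## record the Hamming-taper-weighted energy deposited per
          ## analysis window: that is what the spectrogram stage sees (a
          ## sliver at a window edge is tapered to near-invisibility)
          wdx <- pmin((idx - 1) %/% n1 + 1, nw)
          pos <- (idx - 1) %% n1 + 1
          en <- tapply(rowSums(burst^2) * wham2[pos], wdx, sum)
          artifactRows[[length(artifactRows) + 1]] <<- data.frame(
            artifactId = sprintf("%s.a%d", segId, a),
            segmentId = segId, window = as.integer(names(en)),
            energy = as.numeric(en))
        }
      }
      TriaxSegment(ch, samplingRate = fs, startTime = start,
                   subjectId = subjectId, segmentId = segId)
    })
  })
  ## expected taper-weighted background energy of a 1-s window (all axes);
  ## the reference scale for deciding which windows count as artifactual
  n1 <- round(fs)
  truth <- list(
    backgroundWindowEnergy = 3 * sum(signal::hamming(n1)^2) *
      (noise@broadbandSd^2 + noise@lowFreqMotionSd^2),
    onsetTime = tremor@onsetTime,
    peakFreqAtOnset = tremor@peakFreqAtOnset,
    driftSlope = tremor@driftSlope,
    amplitude = tremor@amplitude,
    artifacts = if (length(artifactRows)) do.call(rbind, artifactRows)
                else data.frame(artifactId = character(0),
                                segmentId = character(0),
                                window = integer(0), energy = numeric(0)))
  TremorSession(segs, subjectId = subjectId, dose = dose,
                metadata = list(truth = truth))
}

#' Ground-truth artifact windows of a simulated session
#'
#' A 1-s analysis window counts as artifactual when the taper-weighted
#' energy a transient deposited into it is at least `minRel` times the
#' expected background window energy. A window brushed by a negligible
#' sliver of a transient (a few samples at the Hamming-tapered window
#' edge, which the spectrogram all but ignores) is not artifactual in any
#' operational sense.
#'
#' @param session a session produced by [simulateSession()].
#' @param minRel minimum deposited energy relative to the expected
#'   background window energy.
#' @return data.frame with `segmentId` and `window` (1-based index of the
#'   1-s window within its segment), one row per artifact window.
#' @export
artifactWindows <- function(session, minRel = 0.5) {
  truth <- session@metadata$truth
  if (is.null(truth)) stop("artifactWindows: session has no simulation truth")
  art <- truth$artifacts
  if (!nrow(art))
    return(data.frame(segmentId = character(0), window = integer(0)))
  keep <- art$energy >= minRel * truth$backgroundWindowEnergy
  unique(art[keep, c("segmentId", "window")])
}

#' Simulate reach-task sessions across doses
#'
#' For each dose level, attempted-reach counts are drawn from a Poisson
#' distribution whose mean is linear in dose (floored at 0), and premature
#' reaches are binomial given a premature fraction linear in dose (clipped
#' to [0, 1]). Dose 0 denotes drug-naive (vehicle) sessions.
#'
#' @param plan a [TaskPlan-class].
#' @return data.frame with one row per session: `dose`, `sessionMinutes`,
#'   `attemptedReaches`, `prematureReaches`.
#' @export
simulateTaskSessions <- function(plan = TaskPlan()) {
  methods::validObject(plan)
  if (length(unique(plan@doses)) < 3)
    stop("simulateTaskSessions: need at least 3 distinct doses")
  withSeed(plan@seed, {
    rows <- lapply(sort(unique(plan@doses)), function(d) {
      nSes <- if (d == 0) plan@nNaiveSessions else plan@nSessionsPerDose
      mu <- max(0, plan@baselineReaches + plan@engagementSlope * d)
      pf <- min(1, max(0, plan@baselinePrematureFrac +
                         plan@prematureSlope * d))
      reaches <- stats::rpois(nSes, mu)
      prem <- stats::rbinom(nSes, reaches, pf)
      data.frame(dose = d,
                 sessionMinutes = if (d == 0) plan@naiveMinutes
                                  else plan@sessionMinutes,
                 attemptedReaches = reaches, prematureReaches = prem)
    })
    do.call(rbind, rows)
  })
}
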