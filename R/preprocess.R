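## Conditioning of raw triaxial segments: linear detrend, 6th-order
## Butterworth high-pass at 1 Hz, and segmentation of continuous streams.

#' Remove the best-fitting line from a series
#'
#' Subtracts the ordinary-least-squares linear trend, leaving a series with
#' zero mean and zero OLS slope.
#'
#' @param x uniformly sampled numeric series, length >= 2.
#' @return Numeric series of the same length.
#' @examples
#' detrendLinear(3 + 0.5 * (1:10))   # all (numerically) zero
#' @export
detrendLinear <- function(x) {
  n <- length(x)
  if (n < 2) stop("detrendLinear: need at least 2 samples")
  tc <- seq_len(n) - (n + 1) / 2
  slope <- sum(tc * x) / sum(tc * tc)
  x - mean(x) - slope * tc
}

## Butterworth high-pass as cascaded biquad (second-order) sections via the
## bilinear transform. A direct 6th-order transfer form is numerically
## fragile at cutoff/Nyquist ratios as small as 1/500 (coefficient
## sensitivity visibly breaks linearity); the cascade is the standard
## robust realization. Odd orders get one first-order section.
butterHighpassSos <- function(order, cutoff, samplingRate) {
  Omega <- tan(pi * cutoff / samplingRate)   # prewarped analog cutoff
  sos <- list()
  nPairs <- order %/% 2
  for (j in seq_len(nPairs)) {
    a <- 2 * sin((2 * j - 1) * pi / (2 * order))  # pole-pair damping
    a0 <- 1 + a * Omega + Omega^2
    sos[[j]] <- list(b = c(1, -2, 1) / a0,
                     a = c(1, 2 * (Omega^2 - 1) / a0,
                           (1 - a * Omega + Omega^2) / a0))
  }
  if (order %% 2 == 1) {
    a0 <- 1 + Omega
    sos[[nPairs + 1]] <- list(b = c(1, -1) / a0,
                              a = c(1, (Omega - 1) / a0))
  }
  sos
}

#' High-pass filter an acceleration series
#'
#' Single-pass (causal) Butterworth high-pass, by default 6th order with a
#' 1 Hz cutoff, removing gravity orientation and slow postural drift while
#' preserving the >= 5 Hz band within 2% amplitude. The filter is realized
#' as cascaded second-order sections, which stays numerically accurate at
#' the very small cutoff-to-Nyquist ratios used here. A zero-phase
#' forward-backward variant is available but doubles the effective order.
#'
#' @param x numeric series (or samples x k matrix, filtered per column).
#' @param samplingRate samples per second.
#' @param cutoff high-pass cutoff in Hz.
#' @param order filter order.
#' @param zeroPhase if TRUE use forward-backward filtering.
#' @return Filtered series, same shape as `x`.
#' @export
highpassFilter <- function(x, samplingRate, cutoff = 1, order = 6,
                           zeroPhase = FALSE) {
  if (cutoff >= samplingRate / 2)
    stop("highpassFilter: cutoff must be below the Nyquist frequency")
  sos <- butterHighpassSos(order, cutoff, samplingRate)
  ff <- function(v) {
    for (s in sos) v <- as.numeric(signal::filter(s$b, s$a, v))
    v
  }
  if (zeroPhase) {
    fwdBwd <- function(v) rev(ff(rev(ff(v))))
    if (is.matrix(x)) apply(x, 2, fwdBwd) else fwdBwd(x)
  } else {
    if (is.matrix(x)) apply(x, 2, ff) else ff(x)
  }
}

#' Condition a raw segment for spectral analysis
#'
#' Per channel: subtract the best linear fit, then (optionally) apply the
#' causal 6th-order 1 Hz Butterworth high-pass, in that order.
#'
#' @param segment a [TriaxSegment-class].
#' @param highpass apply the high-pass stage.
#' @param cutoff,order,zeroPhase passed to [highpassFilter()].
#' @return A conditioned [TriaxSegment-class].
#' @export
preprocessSegment <- function(segment, highpass = TRUE, cutoff = 1,
                              order = 6, zeroPhase = FALSE) {
  ch <- apply(segment@channels, 2, detrendLinear)
  if (highpass)
    ch <- highpassFilter(ch, segment@samplingRate, cutoff = cutoff,
                         order = order, zeroPhase = zeroPhase)
  segment@channels <- ch
  segment
}

#' Condition every segment of a session
#'
#' @param session a [TremorSession-class].
#' @param ... passed to [preprocessSegment()].
#' @return The session with conditioned segments.
#' @export
preprocessSession <- function(session, ...) {
  session@segments <- lapply(session@segments, preprocessSegment, ...)
  session
}

#' Split a continuous recording into analysis segments
#'
#' Continuous streams are cut into consecutive non-overlapping chunks of at
#' most `maxLen` seconds. A trailing remainder is kept only when it is long
#' enough to support at least one Welch window (`minTail`, default 4 s).
#'
#' @param segment a [TriaxSegment-class] of any duration.
#' @param maxLen maximum chunk length in seconds.
#' @param minTail minimum trailing-chunk length in seconds.
#' @return List of [TriaxSegment-class] chunks with correct start times.
#' @examples
#' x <- TriaxSegment(matrix(rnorm(3 * 3000), ncol = 3), samplingRate = 10)
#' vapply(segmentStream(x, maxLen = 120), duration, numeric(1))  # 120 120 60
#' @export
segmentStream <- function(segment, maxLen = 120, minTail = 4) {
  fs <- segment@samplingRate
  n <- nrow(segment@channels)
  if (n < 1) stop("segmentStream: empty segment")
  nPer <- round(maxLen * fs)
  nMin <- round(minTail * fs)
  starts <- seq(1, n, by = nPer)
  out <- list()
  for (i in seq_along(starts)) {
    s <- starts[i]
    e <- min(s + nPer - 1, n)
    len <- e - s + 1
    if (len < nPer && len < nMin) next  # trailing remainder too short
    out[[length(out) + 1]] <- TriaxSegment(
      segment@channels[s:e, , drop = FALSE], samplingRate = fs,
      startTime = segment@startTime + (s - 1) / fs,
      subjectId = segment@subjectId,
      segmentId = sprintf("%s.%d", segment@segmentId, i))
  }
  out
}
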