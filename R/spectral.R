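## Spectral stage: summed 1-s Hamming spectrograms, session-level MAD
## artifact rejection, artifact-free concatenation, Welch PSDs, tremor-band
## peak tracking, motion power ratio and data-driven band selection.

#' @describeIn summedSpectrogram Summed spectrogram of one segment
#'
#' Magnitude-squared short-time Fourier transform with 1-second Hamming
#' windows and no overlap, computed per axis and summed bin-wise over the
#' three axes. A trailing partial second is dropped. Frequency bins are the
#' one-sided DFT grid of a 1-s window (about 1 Hz spacing); window times
#' are window midpoints relative to injection.
#'
#' @param segment a [TriaxSegment-class] of duration >= 1 s.
#' @param ... unused.
#' @return A [SummedSpectrogram-class].
#' @export
setMethod("summedSpectrogram", "TriaxSegment", function(segment, ...) {
  fs <- segment@samplingRate
  n1 <- round(fs)                       # samples per 1-s window
  nw <- nrow(segment@channels) %/% n1
  if (nw < 1) stop("summedSpectrogram: segment shorter than 1 s")
  nb <- n1 %/% 2 + 1
  w <- signal::hamming(n1)
  pow <- matrix(0, nw, nb)
  for (ax in 1:3) {
    m <- matrix(segment@channels[seq_len(nw * n1), ax], n1, nw) * w
    sp <- stats::mvfft(m)[seq_len(nb), , drop = FALSE]
    pow <- pow + t(Mod(sp)^2)
  }
  new("SummedSpectrogram",
      windowTimes = segment@startTime + (seq_len(nw) - 0.5) * (n1 / fs),
      freqBins = (seq_len(nb) - 1) * fs / n1,
      power = pow,
      segmentId = segment@segmentId)
})

#' Spectrograms of every segment in a session
#'
#' @param session a [TremorSession-class].
#' @return List of [SummedSpectrogram-class], one per segment.
#' @export
sessionSpectrograms <- function(session) {
  lapply(segments(session), summedSpectrogram)
}

#' Reject movement-artifact windows by the session-level MAD rule
#'
#' For every 1-s spectrogram window of the session, the summed-over-frequency
#' power is compared against the median over all windows of the session
#' (pooled across segments). Windows deviating by more than `nMad` unscaled
#' median absolute deviations are excluded; a deviation exactly at the
#' threshold is kept.
#'
#' @param spectrograms a [SummedSpectrogram-class] or list of them covering
#'   the whole session.
#' @param nMad rejection threshold in (unscaled) MADs.
#' @return An [ArtifactMask-class] aligned with the concatenated windows.
#' @examples
#' ## powers 1,1,1,1,100: MAD is 0, only the 100-window is excluded
#' @export
rejectArtifacts <- function(spectrograms, nMad = 3) {
  if (is(spectrograms, "SummedSpectrogram"))
    spectrograms <- list(spectrograms)
  if (!length(spectrograms)) stop("rejectArtifacts: no windows in session")
  s <- unlist(lapply(spectrograms, function(sp) rowSums(sp@power)))
  med <- stats::median(s)
  madv <- madRaw(s)
  new("ArtifactMask",
      keep = abs(s - med) <= nMad * madv,
      windowTimes = unlist(lapply(spectrograms, windowTimes)),
      segmentIds = unlist(lapply(spectrograms, function(sp)
        rep(sp@segmentId, nrow(sp@power)))),
      sessionMedianPower = med,
      sessionMadPower = madv)
}

#' Concatenate the artifact-free seconds of a segment
#'
#' Kept 1-s time-domain windows are each linearly detrended (to mitigate the
#' temporal discontinuities created by dropping windows) and concatenated in
#' temporal order, per axis.
#'
#' @param segment the (conditioned) [TriaxSegment-class].
#' @param keep logical vector, one flag per 1-s window of this segment.
#' @return Samples x 3 numeric matrix; zero rows when no window is kept
#'   (the segment is then excluded from the PSD stage).
#' @export
concatenateClean <- function(segment, keep) {
  fs <- segment@samplingRate
  n1 <- round(fs)
  nw <- nrow(segment@channels) %/% n1
  if (length(keep) != nw)
    stop("concatenateClean: mask length ", length(keep),
         " does not match ", nw, " windows")
  kept <- which(keep)
  if (!length(kept)) return(matrix(numeric(0), 0, 3))
  blocks <- lapply(kept, function(wdx) {
    rows <- ((wdx - 1) * n1 + 1):(wdx * n1)
    apply(segment@channels[rows, , drop = FALSE], 2, detrendLinear)
  })
  do.call(rbind, blocks)
}

#' Welch power spectral density
#'
#' Averaged periodogram over Hamming-tapered windows of `windowSec` seconds
#' with 50% overlap. The FFT length is the next power of two at or above the
#' window length (minimum 256), so the frequency spacing is exactly
#' `samplingRate / nfft`; at the study sampling rates of 617, 500 and
#' 1017.3 samples/s with 4-s windows this yields 0.1506, 0.2441 and
#' 0.2484 Hz. Columns of a matrix input (the three axes) are estimated
#' separately and summed. Density scaling is one-sided, so the integral of
#' the PSD over frequency approximates the signal variance.
#'
#' @param x numeric series or samples x 3 matrix of cleaned acceleration.
#' @param samplingRate samples per second.
#' @param windowSec Welch window length in seconds.
#' @param overlap fractional window overlap.
#' @param segmentId,midpointTime carried into the result for bookkeeping.
#' @return A [PSDEstimate-class].
#' @export
welchPsd <- function(x, samplingRate, windowSec = 4, overlap = 0.5,
                     segmentId = "seg", midpointTime = NA_real_) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  n1 <- round(windowSec * samplingRate)
  if (nrow(x) < n1)
    stop("welchPsd: input shorter than one ", windowSec, "-s window")
  nfft <- max(256L, nextPow2(n1))
  hop <- max(1L, floor(n1 * (1 - overlap)))
  starts <- seq(1, nrow(x) - n1 + 1, by = hop)
  w <- signal::hamming(n1)
  scale <- samplingRate * sum(w^2)      # density normalization
  nb <- nfft %/% 2 + 1
  pow <- numeric(nb)
  for (ax in seq_len(ncol(x))) {
    m <- matrix(0, nfft, length(starts))
    for (i in seq_along(starts))
      m[seq_len(n1), i] <- x[starts[i]:(starts[i] + n1 - 1), ax] * w
    sp <- Mod(stats::mvfft(m)[seq_len(nb), , drop = FALSE])^2
    pow <- pow + rowMeans(sp) / scale
  }
  pow[2:(nb - 1)] <- 2 * pow[2:(nb - 1)]  # one-sided (DC and Nyquist once)
  new("PSDEstimate",
      freqs = (seq_len(nb) - 1) * samplingRate / nfft,
      power = pow, nfft = as.integer(nfft), segmentId = segmentId,
      midpointTime = midpointTime, samplingRate = samplingRate)
}

#' Welch PSDs for the artifact-free data of every segment
#'
#' Applies [concatenateClean()] with the session [ArtifactMask-class] and
#' estimates one summed-axis PSD per segment; segments left with less than
#' one Welch window of clean data are skipped.
#'
#' @param session conditioned [TremorSession-class].
#' @param mask session [ArtifactMask-class].
#' @param windowSec,overlap passed to [welchPsd()].
#' @return List of [PSDEstimate-class].
#' @export
sessionPsds <- function(session, mask, windowSec = 4, overlap = 0.5) {
  out <- list()
  for (seg in segments(session)) {
    keep <- mask@keep[mask@segmentIds == seg@segmentId]
    cleaned <- concatenateClean(seg, keep)
    if (nrow(cleaned) < round(windowSec * seg@samplingRate)) next
    out[[length(out) + 1]] <- welchPsd(
      cleaned, seg@samplingRate, windowSec = windowSec, overlap = overlap,
      segmentId = seg@segmentId,
      midpointTime = seg@startTime + duration(seg) / 2)
  }
  out
}

#' Peak frequency within a search band
#'
#' Frequency of the PSD maximum within the half-open band [lo, hi); ties are
#' broken toward the lowest frequency.
#'
#' @param psd a [PSDEstimate-class].
#' @param band numeric (lo, hi) search band in Hz.
#' @return Peak frequency in Hz.
#' @export
peakFrequency <- function(psd, band = c(10, 14)) {
  idx <- which(bandMask(psd@freqs, band))
  if (!length(idx))
    stop("peakFrequency: band [", band[1], ", ", band[2],
         ") is empty on the frequency grid")
  psd@freqs[idx[which.max(psd@power[idx])]]
}

#' Motion power ratio of one spectral power vector
#'
#' Tremor-band power divided by reference-band power (bin sums over
#' half-open bands). The ratio is invariant to any positive rescaling of
#' the spectrum. Zero reference power yields NA (the window is flagged).
#'
#' @param power spectral power on the grid `freqs`.
#' @param freqs frequency grid in Hz.
#' @param bands a [BandDefinition-class].
#' @return Scalar MPR (NA when the reference band carries no power).
#' @examples
#' p <- rep(1, 31)                     # flat spectrum on 0..30 Hz
#' motionPowerRatio(p, 0:30, BandDefinition())   # equal-width bands: 1
#' @export
motionPowerRatio <- function(power, freqs, bands = BandDefinition()) {
  ref <- sum(power[bandMask(freqs, bands@referenceBand)])
  if (!is.finite(ref) || ref <= 0) return(NA_real_)
  sum(power[bandMask(freqs, bands@tremorBand)]) / ref
}

#' Motion power ratio series over the artifact-free windows of a session
#'
#' Computes the per-window MPR for every kept window; masked (artifact)
#' windows carry no MPR. Windows with zero reference power are dropped with
#' a warning.
#'
#' @param spectrograms list of [SummedSpectrogram-class] for the session.
#' @param mask session [ArtifactMask-class].
#' @param bands a [BandDefinition-class].
#' @return An [MPRSeries-class] (not yet baseline-normalized).
#' @export
mprSeries <- function(spectrograms, mask, bands = BandDefinition()) {
  if (is(spectrograms, "SummedSpectrogram"))
    spectrograms <- list(spectrograms)
  times <- unlist(lapply(spectrograms, windowTimes))
  ids <- unlist(lapply(spectrograms, function(sp)
    rep(sp@segmentId, nrow(sp@power))))
  freqs <- spectrograms[[1]]@freqBins
  tIdx <- bandMask(freqs, bands@tremorBand)
  rIdx <- bandMask(freqs, bands@referenceBand)
  pow <- do.call(rbind, lapply(spectrograms, spectralPower))
  mpr <- rowSums(pow[, tIdx, drop = FALSE]) /
    rowSums(pow[, rIdx, drop = FALSE])
  keep <- mask@keep
  bad <- !is.finite(mpr) & keep
  if (any(bad)) {
    warning(sum(bad), " window(s) with zero reference-band power dropped")
    keep <- keep & is.finite(mpr)
  }
  new("MPRSeries", windowTimes = times[keep], segmentIds = ids[keep],
      mpr = mpr[keep], normalizedMpr = rep(NA_real_, sum(keep)),
      bands = bands, baselineMedian = NA_real_)
}

#' Select the tremor band from the session's spectral peaks
#'
#' Designates the tremor band as the modal Welch peak frequency across
#' post-baseline segments, plus/minus `halfWidth`, clipped to the search
#' range. A PSD contributes a peak only when its in-band maximum rises above
#' `noiseFactor` times the median in-band power (otherwise it is treated as
#' noise floor). When a second, well-separated spectral mode reaches at
#' least `prominenceFrac` of the primary mode's power, a secondary band is
#' returned as well (some subjects express two oscillatory modes). If no
#' peak clears the noise floor the default 10-14 Hz band is returned with a
#' warning.
#'
#' @param psds list of [PSDEstimate-class] for the session.
#' @param searchRange (lo, hi) Hz range searched for oscillatory modes.
#' @param halfWidth half-width of the designated band in Hz.
#' @param prominenceFrac secondary-mode threshold, fraction of primary power.
#' @param noiseFactor peak-to-median power ratio required to count a peak.
#' @param baselineCutoff seconds; only PSDs with midpoints beyond this
#'   contribute.
#' @return A [BandDefinition-class].
#' @export
selectTremorBand <- function(psds, searchRange = c(8, 16), halfWidth = 2,
                             prominenceFrac = 0.25, noiseFactor = 3,
                             baselineCutoff = 900) {
  post <- Filter(function(p) isTRUE(p@midpointTime > baselineCutoff), psds)
  if (!length(post))
    stop("selectTremorBand: no post-baseline PSD available")
  fallback <- function() {
    warning("no spectral peak above the noise floor; using default 10-14 Hz band")
    BandDefinition(c(10, 14))
  }
  peaks <- numeric(0)
  for (p in post) {
    idx <- which(bandMask(p@freqs, searchRange))
    if (!length(idx)) next
    pk <- max(p@power[idx])
    if (pk > noiseFactor * stats::median(p@power[idx]))
      peaks <- c(peaks, p@freqs[idx[which.max(p@power[idx])]])
  }
  if (!length(peaks)) return(fallback())
  tab <- table(peaks)
  center <- as.numeric(names(tab)[which.max(tab)])  # modal; ties -> lowest
  lo <- max(searchRange[1], center - halfWidth)
  hi <- min(searchRange[2], center + halfWidth)
  ## secondary mode: strongest well-separated local maximum of the mean PSD
  secondary <- numeric(0)
  mp <- rowMeans(vapply(post, function(p) p@power, post[[1]]@power))
  freqs <- post[[1]]@freqs
  idx <- which(bandMask(freqs, searchRange))
  outside <- idx[freqs[idx] < lo - halfWidth / 2 | freqs[idx] >= hi + halfWidth / 2]
  if (length(outside)) {
    primaryPow <- max(mp[idx[freqs[idx] >= lo & freqs[idx] < hi]])
    j <- outside[which.max(mp[outside])]
    isLocalMax <- mp[j] >= mp[max(1, j - 1)] && mp[j] >= mp[min(length(mp), j + 1)]
    if (isLocalMax && mp[j] >= prominenceFrac * primaryPow)
      secondary <- c(max(searchRange[1], freqs[j] - halfWidth),
                     min(searchRange[2], freqs[j] + halfWidth))
  }
  BandDefinition(c(lo, hi), secondaryBand = secondary)
}
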