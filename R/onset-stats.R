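## Onset statistics: baseline normalization, per-segment Wilcoxon
## signed-rank tests with Benjamini-Hochberg control, tremor-onset
## extraction, bootstrap medians and the peak-frequency drift regression.

#' Baseline MPR statistics
#'
#' All data recorded before injection or within 15 minutes (900 s) of it are
#' treated as baseline activity; the pooled median MPR over those windows
#' defines the normalization divisor and the null value for the per-segment
#' tests.
#'
#' @param mpr an [MPRSeries-class] covering the session.
#' @param baselineCutoff baseline boundary in seconds post-injection
#'   (window midpoints <= this, including negative pre-injection times,
#'   are baseline).
#' @return List with `baselineMedianMpr`, `nBaselineWindows` and
#'   `baselineCutoff`.
#' @export
baselineMedian <- function(mpr, baselineCutoff = 900) {
  idx <- mpr@windowTimes <= baselineCutoff
  if (!any(idx))
    stop("baselineMedian: no baseline windows (<= ", baselineCutoff,
         " s); session is unanalyzable")
  list(baselineMedianMpr = stats::median(mpr@mpr[idx]),
       nBaselineWindows = sum(idx),
       baselineCutoff = baselineCutoff)
}

#' Normalize an MPR series to its baseline median
#'
#' After normalization the baseline windows have median exactly 1 by
#' construction.
#'
#' @param mpr an [MPRSeries-class].
#' @param baseline result of [baselineMedian()] (computed if omitted).
#' @return The [MPRSeries-class] with `normalizedMpr` filled in.
#' @export
normalizeMpr <- function(mpr, baseline = baselineMedian(mpr)) {
  mpr@normalizedMpr <- mpr@mpr / baseline$baselineMedianMpr
  mpr@baselineMedian <- baseline$baselineMedianMpr
  mpr
}

#' Wilcoxon signed-rank test of a segment against the baseline null
#'
#' Two-sided one-sample Wilcoxon signed-rank test of the normalized MPR
#' values of one segment against the null value 1 (the normalized baseline
#' median). Zero differences are discarded (classical Wilcoxon convention);
#' the exact null distribution is used for n <= 25 without ties, and the
#' normal approximation with tie correction otherwise. The direction flag
#' is the sign of the median difference and is reported separately from the
#' two-sided p-value.
#'
#' @param values normalized MPR values of one segment.
#' @param nullValue null value tested against.
#' @return List with `pValue` and `direction` ("above", "below" or "none").
#' @examples
#' testSegment(c(1.2, 1.4, 1.1, 1.6, 1.3, 1.5))  # exact p = 2/2^6 = 0.03125
#' @export
testSegment <- function(values, nullValue = 1) {
  if (!length(values)) stop("testSegment: empty segment")
  d <- values - nullValue
  md <- stats::median(d)
  eps <- 1e-12 * max(abs(values), 1)  # guard against fp noise in the median
  direction <- if (md > eps) "above" else if (md < -eps) "below" else "none"
  d <- d[d != 0]
  if (!length(d)) return(list(pValue = 1, direction = "none"))
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  p <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE)$p.value)
  list(pValue = p, direction = direction)
}

#' Benjamini-Hochberg rejection flags
#'
#' Standard step-up procedure at false discovery rate `fdr`: with ordered
#' p-values p(1) <= ... <= p(m), reject all hypotheses with p <= p(k*) where
#' k* is the largest k such that p(k) <= (k/m) * fdr.
#'
#' @param pValues numeric p-values in [0, 1].
#' @param fdr target false discovery rate (the pipeline default 1e-4 is
#'   deliberately conservative).
#' @return Logical rejection flags in the original order.
#' @export
bhAdjust <- function(pValues, fdr = 1e-4) {
  if (!length(pValues)) return(logical(0))
  if (any(pValues < 0 | pValues > 1, na.rm = TRUE))
    stop("bhAdjust: p-values must lie in [0, 1]")
  stats::p.adjust(pValues, method = "BH") <= fdr
}

#' Bootstrap confidence interval for a segment median
#'
#' Seeded percentile bootstrap of the median. The interval is widened, if
#' necessary, to contain the observed median.
#'
#' @param values numeric sample.
#' @param level confidence level.
#' @param nBoot bootstrap resamples.
#' @param seed optional RNG seed (caller's stream is left untouched).
#' @return Numeric (low, high).
#' @export
ciSegmentMedian <- function(values, level = 0.95, nBoot = 1000, seed = NULL) {
  med <- stats::median(values)
  if (length(values) < 2) return(c(med, med))
  boot <- withSeed(seed, {
    n <- length(values)
    idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), n, nBoot)
    apply(matrix(values[idx], n, nBoot), 2, stats::median)
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  c(min(ci[1], med), max(ci[2], med))
}

#' Per-segment MPR statistics with FDR control
#'
#' For each segment: the median normalized MPR (the segment's time value is
#' the midpoint of its windows), a bootstrap 95% confidence interval, the
#' two-sided signed-rank p-value against 1, the direction of the shift, and
#' the Benjamini-Hochberg rejection flag across all segments of the session.
#'
#' @param mpr a baseline-normalized [MPRSeries-class].
#' @param fdr false discovery rate for [bhAdjust()].
#' @param level,nBoot,seed passed to [ciSegmentMedian()] (each segment's CI
#'   is seeded deterministically from `seed`).
#' @return data.frame with one row per segment: `segmentId`,
#'   `midpointTime` (s), `nWindows`, `medianNormalizedMpr`, `ciLow`,
#'   `ciHigh`, `pValue`, `bhReject`, `direction`.
#' @export
segmentStats <- function(mpr, fdr = 1e-4, level = 0.95, nBoot = 1000,
                         seed = 1L) {
  if (all(is.na(mpr@normalizedMpr)))
    stop("segmentStats: MPR series is not baseline-normalized")
  ids <- unique(mpr@segmentIds)
  rows <- lapply(seq_along(ids), function(i) {
    sel <- mpr@segmentIds == ids[i]
    v <- mpr@normalizedMpr[sel]
    tt <- mpr@windowTimes[sel]
    ts <- testSegment(v, nullValue = 1)
    ci <- ciSegmentMedian(v, level = level, nBoot = nBoot,
                          seed = if (is.null(seed)) NULL else seed + i)
    data.frame(segmentId = ids[i],
               midpointTime = (min(tt) + max(tt)) / 2,
               nWindows = sum(sel),
               medianNormalizedMpr = stats::median(v),
               ciLow = ci[1], ciHigh = ci[2],
               pValue = ts$pValue, direction = ts$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bhReject <- bhAdjust(out$pValue, fdr = fdr)
  out[order(out$midpointTime),
      c("segmentId", "midpointTime", "nWindows", "medianNormalizedMpr",
        "ciLow", "ciHigh", "pValue", "bhReject", "direction")]
}

#' Detect tremor onset
#'
#' Tremor onset is the earliest post-baseline segment whose median
#' normalized MPR differs significantly from baseline after FDR control,
#' with the shift in the "above" direction; its midpoint is reported in
#' minutes post-injection. When no such segment exists the result carries
#' NA (no onset).
#'
#' @param stats data.frame from [segmentStats()].
#' @param baselineCutoff seconds; only segments with midpoints beyond this
#'   qualify.
#' @return An [OnsetResult-class].
#' @export
detectOnset <- function(stats, baselineCutoff = 900) {
  cand <- stats[stats$bhReject & stats$direction == "above" &
                  stats$midpointTime > baselineCutoff, , drop = FALSE]
  if (!nrow(cand))
    return(new("OnsetResult", onsetTime = NA_real_,
               onsetSegmentId = NA_character_))
  first <- cand[which.min(cand$midpointTime), ]
  new("OnsetResult", onsetTime = first$midpointTime / 60,
      onsetSegmentId = first$segmentId)
}

#' Linear peak-frequency drift regression
#'
#' Ordinary least squares fit of tracked peak frequency against time
#' (minutes post-injection), restricted to points after the wash-in cutoff
#' (15 minutes) and after outlier exclusion: (a) peaks saturated at the
#' search-band boundary are dropped, then (b) one pass of residual
#' screening removes points whose OLS residual exceeds `nMadResid`
#' normal-consistent MADs (about `nMadResid` sigma) of the residuals, after
#' which the line is refit. The normal-consistent scaling matters here:
#' screening at unscaled MADs trims several percent of legitimate points
#' and visibly narrows the confidence interval below nominal coverage. The
#' 95% confidence interval on the slope comes from the t distribution of
#' the OLS slope estimator.
#'
#' @param timesMin peak times in minutes post-injection.
#' @param freqs tracked peak frequencies in Hz.
#' @param cutoffMin wash-in cutoff in minutes.
#' @param band optional (lo, hi) search band used for the peaks; peaks
#'   within `edgeTol` of either boundary are treated as saturated.
#' @param edgeTol band-edge tolerance in Hz (use the PSD bin spacing).
#' @param nMadResid residual screening threshold in unscaled MADs.
#' @param level confidence level for the slope interval.
#' @return A [DriftFit-class].
#' @export
fitDrift <- function(timesMin, freqs, cutoffMin = 15, band = NULL,
                     edgeTol = 0, nMadResid = 3, level = 0.95) {
  stopifnot(length(timesMin) == length(freqs))
  sel <- which(timesMin > cutoffMin)
  excluded <- integer(0)
  if (!is.null(band)) {
    edge <- sel[freqs[sel] <= band[1] + edgeTol |
                  freqs[sel] >= band[2] - edgeTol]
    excluded <- c(excluded, edge)
    sel <- setdiff(sel, edge)
  }
  if (length(sel) < 3)
    stop("fitDrift: fewer than 3 usable points after the ", cutoffMin,
         "-min cutoff")
  fit <- stats::lm(freqs[sel] ~ timesMin[sel])
  r <- stats::residuals(fit)
  madr <- stats::mad(r)   # normal-consistent: threshold ~ nMadResid sigma
  tol <- 1e-9 * max(abs(freqs[sel]), 1)   # skip screening on an exact line
  if (madr > tol) {
    drop <- abs(r) > nMadResid * madr
    if (any(drop)) {
      excluded <- c(excluded, sel[drop])
      sel <- sel[!drop]
      if (length(sel) < 3)
        stop("fitDrift: fewer than 3 points survive outlier screening")
      fit <- stats::lm(freqs[sel] ~ timesMin[sel])
    }
  }
  cf <- stats::coef(fit)
  ci <- tryCatch(suppressWarnings(stats::confint(fit, level = level)[2, ]),
                 error = function(e) c(cf[2], cf[2]))
  if (any(!is.finite(ci))) ci <- c(cf[2], cf[2])
  new("DriftFit", slope = unname(cf[2]), intercept = unname(cf[1]),
      slopeCi = unname(ci), nPoints = length(sel),
      excluded = as.integer(sort(excluded)))
}
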