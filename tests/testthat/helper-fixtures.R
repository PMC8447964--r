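# Fixture builders and independent oracles shared across test files.
# All fixtures are generated in code; nothing is read from disk.

# Pure-tone triaxial segment (optionally noisy), projected on given axes.
toneSegment <- function(freq, fs = 500, durSec = 10, amp = 1,
                        axes = c(1, 0, 0), startTime = 0, noiseSd = 0,
                        id = "tone") {
  t <- (0:(round(durSec * fs) - 1)) / fs
  sig <- amp * sin(2 * pi * freq * t)
  ch <- outer(sig, axes)
  if (noiseSd > 0) ch <- ch + matrix(rnorm(length(t) * 3, sd = noiseSd),
                                     ncol = 3)
  TriaxSegment(ch, samplingRate = fs, startTime = startTime, segmentId = id)
}

# Compact session plan for fast end-to-end runs (2 baseline + 2 post
# segments); not the study-condition default.
smallPlan <- function(seed = 1, fs = 500) {
  SessionPlan(samplingRate = fs,
              schedule = data.frame(start = c(-120, 60, 960, 1080),
                                    duration = 60),
              seed = seed)
}

# Build a SummedSpectrogram directly from a vector of per-window summed
# powers (single frequency bin), for artifact-rule tests.
powerSpectrogram <- function(powers, id = "p", t0 = 0) {
  new("SummedSpectrogram",
      windowTimes = t0 + seq_along(powers) - 0.5,
      freqBins = 0,
      power = matrix(powers, ncol = 1),
      segmentId = id)
}

# Exhaustive-enumeration oracle for the one-sample two-sided Wilcoxon
# signed-rank test (no zeros, no ties assumed). Enumerates all 2^n sign
# assignments of the ranked absolute differences.
wilcoxEnumOracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(vs <= v), mean(vs >= v)))
}

# Brute-force step-up Benjamini-Hochberg oracle.
bhStepUpOracle <- function(p, fdr) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= (seq_len(m) / m) * fdr)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# Steady-state amplitude of a sinusoid at frequency f in series x
# (projection on the sin/cos pair), for filter-response checks.
sineAmplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  cf <- coef(lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t)))
  sqrt(cf[2]^2 + cf[3]^2)
}
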