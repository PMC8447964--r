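Package: tremorquant
Title: Quantification of Drug-Induced Tremor from Wrist Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying pharmacologically induced tremor from
    episodic triaxial wrist accelerometry. Implements linear detrending and
    high-pass conditioning of raw acceleration, summed short-time Fourier
    spectrograms with robust (median absolute deviation) movement-artifact
    rejection, Welch power spectral density estimation with tremor-band peak
    tracking, the tremor-band motion power ratio statistic, nonparametric
    tremor-onset detection (Wilcoxon signed-rank tests with
    Benjamini-Hochberg false discovery rate control), linear peak-frequency
    drift regression, and dose-response summaries for a self-paced cued
    reaching task. Includes a seeded synthetic-session generator emulating
    the statistical structure of primate harmaline-tremor recordings so the
    full pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
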