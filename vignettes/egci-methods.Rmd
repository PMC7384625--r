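---
title: "Methods behind the Ecoacoustic Global Complexity Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the Ecoacoustic Global Complexity Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egci)
```

## The model

An ecoacoustic signal is treated as the superposition of a deterministic
component (animal vocalizations, rhythmic patterns) and a stochastic
component (environmental noise). The package summarizes this balance with a
single pair of Information-Theory quantifiers derived from the signal's
second-order structure:

1. the unbiased autocorrelation function up to `tau_max` lags, with the
   segment mean and sample standard deviation (denominator N − 1) computed
   once over the whole segment, so the lag-0 coefficient is exactly 1;
2. its symmetric Toeplitz matrix, whose dimension equals the lag count, so
   the resulting eigenvalue histogram has exactly `M = tau_max` bins and the
   entropy normalization `log M` is consistent with the bin count;
3. the singular value decomposition of that matrix, whose normalized
   singular spectrum is read as a probability mass function `P`;
4. the normalized Von Neumann entropy `H[P]`, the Jensen–Shannon divergence
   `J[P, Pe]` from the uniform reference `Pe`, and the statistical
   complexity `C = Q0 · J · H` — the EGCI.

The representation assumes wide-sense stationarity within a segment: the
autocorrelation matrix only captures second-order, time-invariant
structure. Segments short enough to be locally stationary (the 22-s field
convention) are the intended unit of analysis. Because the autocorrelation
standardizes by mean and standard deviation, the index is invariant to
recording gain and DC offset; this is verified numerically in the test
suite.

Interpretation of the plane: strongly autocorrelated signals (red noise,
rain) concentrate the singular spectrum and drive `H` toward 0;
uncorrelated noise flattens it (`H` toward 1, `C` toward 0); mixtures of
periodic patterns and noise produce intermediate entropy with maximal
divergence, hence the highest complexity. Both extremes of order have zero
complexity by construction.

## Parameters that matter

* `tau_max` (dimensionless lag count, default **512**): the single free
  parameter. It is simultaneously the autocorrelation depth, the matrix
  dimension, and the histogram size. Small values compress the plane's
  usable band and blur distinct signals; large values inflate entropy by
  fragmenting acoustic patterns. The hard validity constraint
  `tau_max <= N/2` is enforced. 512 is the reference setting for 22-s
  segments at 44.1 kHz and is what the boundary and fingerprint defaults
  assume.
* `segment_s` (seconds, default **22**): the monitoring segment length; any
  positive value works provided `tau_max <= fs * segment_s / 2`.
* `nfft` (samples, default **512**) and Hann window, no overlap: the
  spectrogram substrate of the comparison indices.
* ADI/AEI: ten equal bands over 0–10 kHz, binarization threshold −50 dB
  relative to full scale. ADI is reported in nats (maximum `log 10`≈ 2.303);
  no further normalization is applied.
* NDSI: biophony band 2–8 kHz, anthropophony 0–2 and 8–10 kHz, each scanned
  in 1-kHz sub-bands; the index is oriented so +1 means a soundscape free of
  anthropogenic energy. The quotient is symmetric, so the orientation is a
  sign convention; the biophony-positive form matches the stated meaning of
  the extremes.
* BI: 2–8 kHz band, time-averaged spectrum in dB offset to a zero band
  minimum, trapezoidal integration over frequency in kHz.

## Plane geometry

For fixed `M`, all histograms live between two boundary curves attained by
one-parameter extremal families: minimum complexity by
`{p, (1−p)/(M−1), …}`, maximum complexity by families with one free mass,
`K − 1` equal masses and `M − K` empty bins. The families with support
`K = 2 … M` tile the entropy axis into disjoint intervals
`[log(K−1)/log M, log K/log M]`, and within each family the entropy is
strictly monotone in the free mass. Both curves are therefore evaluated
*exactly* at any `H` by bracketed root-finding (tolerance 1e−13) on closed
forms, rather than by interpolating a sampled grid — this is what makes the
Monte-Carlo containment property testable at a 1e−9 tolerance. The sampled
`hxc_boundaries()` grid exists for plotting and export. The construction is
validated two ways: the closed forms are checked against the generic
quantifier pipeline on explicit family vectors, and 10^4 random histograms
are checked to fall inside the band.

The colored-noise reference curve is drawn by simulating `1/f^alpha` noise
for `alpha` from 0 to 2 in steps of 0.1 (10 seeds per point, 2^17 samples
at 44.1 kHz by default) and averaging the resulting plane coordinates.

## The synthetic-data generator

The package is exercised entirely on synthetic audio, by design:

* **Colored noise** is produced by spectral shaping — white Gaussian noise
  whose Fourier coefficients are scaled by `|f|^(−alpha/2)` with the DC term
  zeroed, inverse-transformed and standardized. This is exact in
  expectation for the target power law; the generator's spectral exponent
  is verified by an independent periodogram fit (slope recovered within
  ±0.1 at `alpha = 2` over 10 seeds of 2^17 samples).
* **Scenes** superpose tones, linear chirps and Hann-windowed pulse trains
  on colored noise; when a target SNR is given the noise is rescaled so the
  total deterministic-to-stochastic power ratio matches it in dB. The SNR
  convention is total power, and the reference noise condition is 0 dB.
* **Monitoring streams** emulate a duty-cycled autonomous recorder: 22-s
  segments timestamped over multiple days, each rendered from a diel
  profile mapping decimal hour to a scene description; transient events
  (e.g. a half-hour rain shower as `alpha ~ 2` noise) are expressed in the
  profile itself. The `segments_per_slot` option records a fixed number of
  segments at each half-hour slot, the standard duty-cycling of long
  deployments.

What the generator does *not* emulate: realistic animal call morphology,
frequency-modulated choruses, propagation and reverberation, microphone
self-noise, or non-stationarity within a segment. Passing tests on this
material demonstrate the correctness of the quantifiers and the qualitative
geometry of the plane (ordering of noise classes, peak detection in diel
profiles); they do not certify ecological validity on real recordings,
which requires field data.

## Numerical choices

* Natural logarithms everywhere; each entropy is normalized by `log M`, so
  the base cancels and only consistency matters.
* `0 · log 0 := 0` (continuity limit). Near-singular Toeplitz matrices do
  occur — a pure tone's matrix has numerical rank ~2 — so exact zeros in the
  spectrum must be admissible.
* Singular values rather than signed eigenvalues; for these symmetric
  near-positive-definite matrices the two coincide, and the test suite
  checks the SVD route against a symmetric eigendecomposition to 1e−10.
* The ACF is computed via FFT (zero-padding to at least 2N, circular
  autocovariance, per-lag unbiased correction); equality with the direct
  O(N·tau) sum is enforced to 1e−10 relative error in tests. The unbiased
  correction can push late-lag coefficients marginally outside [−1, 1];
  values enter the matrix unclipped.
* `Q0` uses the closed form obtained by maximizing the divergence at the
  degenerate histogram,
  `Q0 = −2 log M / [((M+1)/M) log(M+1) − 2 log(2M) + log M]`;
  its defining property `Q0 · J[P_deg, Pe] = 1` is unit-tested across `M`
  up to 1024, so any error in the derivation would be caught.
* Degenerate (constant) segments have no defined autocorrelation; batch
  processing skips them with a warning instead of failing the run.
* WAV I/O is a minimal RIFF reader/writer (integer PCM 16/24/32 and
  float32, multichannel averaged to mono). Timestamps come from
  `<prefix>_YYYYMMDD_HHMMSS` file names when present, else file mtime.

## Aggregation conventions

Centroids are arithmetic means per group; dispersion is reported both as
sample standard deviation and as a normal-approximation 95% confidence
half-width (`1.96 s/√n`), since either may be the quantity of interest when
plotting error bars; single-point groups report zero dispersion. Hour
extraction uses the timestamp's zone with no DST adjustment (field sites
run on fixed offsets). Daily fingerprints always return 48 half-hour bins;
bins without segments are flagged (`n = 0`) and never interpolated, so
recorder outages remain visible.

## Problem sizes in the test suite

The packaged checks run at desk scale by choice: noise-exponent recovery
uses 10 seeds of 2^17 samples; plane containment uses 10^4 random
histograms at `M = 64`; the plane-ordering check uses 2^17-sample signals
at `tau_max = 512`; and the two-day fingerprint study uses a duty-cycled
stream (two 22-s segments per half-hour slot at 8 kHz, 192 segments,
`tau_max = 512`) with activity peaks injected at 07:00 and 17:00. These
sizes reproduce the qualitative structure stably across seeds while keeping
the whole suite in the minutes range.

## Known limitations

* Stationarity within a segment is assumed, not tested; strongly transient
  segments (a single close call in silence) land at low entropy like
  colored noise does.
* The index is blind to absolute level — a distant chorus and a close one
  with the same correlation structure map to the same point.
* FLAC and MP3 inputs are not supported; recordings should be provided as
  WAV.
* The comparison indices follow their original published formulations with
  the parameter conventions listed above; site-specific retunings (other
  band limits, thresholds) are exposed as arguments but not validated
  against any particular ecosystem.
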