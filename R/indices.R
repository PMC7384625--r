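#' Power spectrogram of a signal
#'
#' Magnitude-squared short-time Fourier transform (Hann window), the common
#' substrate for the classical acoustic indices. Defaults follow the
#' comparison setting: 512-point FFT, no overlap.
#'
#' @param x an [acoustic_signal] or numeric vector.
#' @param nfft FFT length (signal must be at least this long).
#' @param overlap samples of overlap between frames (default 0).
#' @param fs sampling rate, required for bare numeric input.
#' @return object of class `acoustic_spectrogram`: list with `power`
#'   (frequency x time matrix), `f` (bin centers, Hz), `t` (frame times, s),
#'   `fs`, `nfft`, `window`.
#' @export
acoustic_spectrogram <- function(x, nfft = 512, overlap = 0, fs = NULL) {
  x <- as_signal(x, fs)
  if (length(x$samples) < nfft)
    stop("signal shorter than one FFT frame (", nfft, " samples)",
         call. = FALSE)
  sg <- signal::specgram(x$samples, n = nfft, Fs = x$fs,
                         window = signal::hanning(nfft), overlap = overlap)
  structure(
    list(power = Mod(sg$S)^2, f = as.numeric(sg$f), t = as.numeric(sg$t),
         fs = x$fs, nfft = nfft, window = "hann"),
    class = "acoustic_spectrogram"
  )
}

#' @export
print.acoustic_spectrogram <- function(x, ...) {
  cat(sprintf("<acoustic_spectrogram> %d bins x %d frames (nfft %d, %s)\n",
              nrow(x$power), ncol(x$power), x$nfft, x$window))
  invisible(x)
}

as_spectrogram <- function(x, nfft = 512, fs = NULL) {
  if (inherits(x, "acoustic_spectrogram")) return(x)
  acoustic_spectrogram(x, nfft = nfft, fs = fs)
}

#' Acoustic Complexity Index (ACI)
#'
#' Rate of spectral change: for each frequency band of the spectrogram the
#' absolute frame-to-frame intensity differences are summed and divided by
#' the band's total intensity; the index is the sum over bands (one temporal
#' block). Scale-invariant by construction; a time-constant spectrogram
#' scores 0. Bands with no energy contribute 0.
#'
#' @param x an `acoustic_spectrogram` (or a signal, transformed with the
#'   default settings). Needs at least 2 frames.
#' @param nfft,fs used when `x` is a signal.
#' @return nonnegative scalar.
#' @export
aci <- function(x, nfft = 512, fs = NULL) {
  sp <- as_spectrogram(x, nfft, fs)
  if (ncol(sp$power) < 2)
    stop("ACI needs at least 2 spectrogram frames", call. = FALSE)
  per_band <- apply(sp$power, 1, function(I) {
    tot <- sum(I)
    if (tot == 0) 0 else sum(abs(diff(I))) / tot
  })
  sum(per_band)
}

#' Spectral and temporal entropies, and the acoustic entropy index
#'
#' `spectral_entropy()` (Hf) treats the time-averaged normalized power
#' spectrum as a histogram and returns its Shannon entropy normalized to
#' \[0, 1\]; white noise scores near 1, a pure tone near 0.
#' `temporal_entropy()` (Ht) does the same with the analytic-signal
#' amplitude envelope; a constant-envelope tone scores near 1, a lone click
#' near 0. `acoustic_entropy()` is their product Ha = Hf x Ht.
#'
#' @param x an [acoustic_signal] or numeric vector (non-constant).
#' @param nfft FFT length for the spectral estimate.
#' @param fs sampling rate for bare numeric input.
#' @return entropy in `[0, 1]`.
#' @name entropy_indices
NULL

#' @rdname entropy_indices
#' @export
spectral_entropy <- function(x, nfft = 512, fs = NULL) {
  sp <- as_spectrogram(x, nfft, fs)
  m <- rowMeans(sp$power)
  tot <- sum(m)
  if (tot == 0) stop("degenerate signal: no spectral energy", call. = FALSE)
  shannon(m / tot) / log(length(m))
}

# Amplitude envelope via the analytic signal (FFT construction of the
# Hilbert transform).
amplitude_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' @rdname entropy_indices
#' @export
temporal_entropy <- function(x, fs = NULL) {
  x <- as_signal(x, fs)
  if (stats::sd(x$samples) == 0)
    stop("degenerate signal: constant amplitude", call. = FALSE)
  env <- amplitude_envelope(x$samples)
  shannon(env / sum(env)) / log(length(env))
}

#' @rdname entropy_indices
#' @export
acoustic_entropy <- function(x, nfft = 512, fs = NULL) {
  x <- as_signal(x, fs)
  spectral_entropy(x, nfft) * temporal_entropy(x)
}

# Band occupancy shared by ADI and AEI: normalize the power spectrogram to
# 0 dB full scale, binarize at threshold_db, count above-threshold cells in
# equal bands spanning [0, fmax].
band_occupancy <- function(sp, bands, fmax, threshold_db) {
  if (sp$fs / 2 < fmax)
    stop("spectrogram Nyquist (", sp$fs / 2, " Hz) below fmax = ", fmax,
         call. = FALSE)
  pk <- max(sp$power)
  if (pk == 0) return(rep(0, bands))
  db <- 10 * log10(sp$power / pk + .Machine$double.xmin)
  binary <- db >= threshold_db
  edges <- seq(0, fmax, length.out = bands + 1)
  band_of <- findInterval(sp$f, edges, rightmost.closed = FALSE,
                          left.open = FALSE)
  occ <- vapply(seq_len(bands), function(b) sum(binary[band_of == b, ]),
                numeric(1))
  occ
}

#' Acoustic Diversity Index (ADI)
#'
#' Shannon entropy (nats) of the above-threshold occupancy spread over
#' `bands` equal frequency bands in \[0, `fmax`\]: the spectrogram is
#' normalized to 0 dB full scale, binarized at `threshold_db`, occupancy is
#' accumulated per band and converted to a probability vector. Maximum is
#' `log(bands)` (about 2.303 for ten bands); all-empty occupancy returns 0.
#'
#' @param x an `acoustic_spectrogram` or signal.
#' @param bands number of equal bands (default 10).
#' @param fmax upper frequency limit in Hz (default 10000); requires
#'   `fs/2 >= fmax`.
#' @param threshold_db binarization threshold relative to full scale
#'   (default -50).
#' @param nfft,fs used when `x` is a signal.
#' @return entropy in nats, `[0, log(bands)]`.
#' @export
adi <- function(x, bands = 10, fmax = 10000, threshold_db = -50,
                nfft = 512, fs = NULL) {
  occ <- band_occupancy(as_spectrogram(x, nfft, fs), bands, fmax,
                        threshold_db)
  tot <- sum(occ)
  if (tot == 0) return(0)
  shannon(occ / tot)
}

#' Acoustic Evenness Index (AEI)
#'
#' Gini coefficient of the same band occupancies as [adi()]: 0 for a
#' perfectly even distribution across bands, `(bands - 1)/bands` (0.9 for
#' ten bands) when all occupancy falls in a single band. Uses the
#' mean-absolute-difference estimator without small-sample correction.
#'
#' @inheritParams adi
#' @return Gini coefficient in `[0, 1]`.
#' @export
aei <- function(x, bands = 10, fmax = 10000, threshold_db = -50,
                nfft = 512, fs = NULL) {
  occ <- band_occupancy(as_spectrogram(x, nfft, fs), bands, fmax,
                        threshold_db)
  tot <- sum(occ)
  if (tot == 0) return(0)
  sum(abs(outer(occ, occ, `-`))) / (2 * length(occ) * tot)
}

#' Normalized Difference Soundscape Index (NDSI)
#'
#' Ratio of biophonic to anthropophonic spectral energy. The time-averaged
#' PSD is accumulated in 1-kHz sub-bands; biophony is the strongest sub-band
#' within 2-8 kHz, anthrophony the strongest within 0-2 and 8-10 kHz, and
#' the index is `(biophony - anthrophony) / (biophony + anthrophony)`:
#' +1 for a soundscape free of anthropogenic disturbance, -1 for one
#' dominated by it.
#'
#' @param x an `acoustic_spectrogram` or signal.
#' @param bio_band biophonic frequency range in Hz (default `c(2000, 8000)`).
#' @param anthro_bands list of anthropophonic ranges (default 0-2 kHz and
#'   8-10 kHz).
#' @param nfft,fs used when `x` is a signal.
#' @return index in `[-1, 1]`.
#' @export
ndsi <- function(x, bio_band = c(2000, 8000),
                 anthro_bands = list(c(0, 2000), c(8000, 10000)),
                 nfft = 512, fs = NULL) {
  sp <- as_spectrogram(x, nfft, fs)
  psd <- rowMeans(sp$power)
  subband_power <- function(range) {
    edges <- seq(range[1], range[2], by = 1000)
    vapply(seq_len(length(edges) - 1), function(i) {
      sum(psd[sp$f >= edges[i] & sp$f < edges[i + 1]])
    }, numeric(1))
  }
  bio <- max(subband_power(bio_band))
  anthro <- max(unlist(lapply(anthro_bands, subband_power)))
  if (bio + anthro == 0)
    stop("no spectral energy in the NDSI bands", call. = FALSE)
  (bio - anthro) / (bio + anthro)
}

#' Bioacoustic Index (BI)
#'
#' Area under the time-averaged spectrum in dB over the songbird band
#' (default 2-8 kHz), offset so the band minimum sits at 0 dB; trapezoidal
#' integration over frequency in kHz. A spectrally flat signal scores 0;
#' adding an in-band tone increases the index.
#'
#' @param x an `acoustic_spectrogram` or signal.
#' @param band frequency range in Hz (default `c(2000, 8000)`).
#' @param nfft,fs used when `x` is a signal.
#' @return area in dB kHz (>= 0).
#' @export
bi <- function(x, band = c(2000, 8000), nfft = 512, fs = NULL) {
  sp <- as_spectrogram(x, nfft, fs)
  sel <- sp$f >= band[1] & sp$f <= band[2]
  if (sum(sel) < 2)
    stop("fewer than 2 spectrogram bins in the BI band", call. = FALSE)
  m <- rowMeans(sp$power)[sel]
  db <- 10 * log10(pmax(m, .Machine$double.xmin))
  v <- db - min(db)
  f_khz <- sp$f[sel] / 1000
  sum(diff(f_khz) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' All comparison indices for one segment
#'
#' Computes the six classical indices (ACI, Ha with its Hf and Ht factors,
#' ADI, AEI, NDSI, BI) from a single spectrogram pass plus the signal-domain
#' entropies. An index that fails on a given segment (e.g. NDSI on a silent
#' one) is reported as `NA`, never as zero.
#'
#' @param x an [acoustic_signal] or numeric vector.
#' @param nfft FFT length (default 512).
#' @param fs sampling rate for bare numeric input.
#' @return one-row data frame with columns `aci`, `ha`, `hf`, `ht`, `adi`,
#'   `aei`, `ndsi`, `bi`.
#' @export
index_set <- function(x, nfft = 512, fs = NULL) {
  x <- as_signal(x, fs)
  sp <- tryCatch(acoustic_spectrogram(x, nfft = nfft), error = function(e) e)
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  if (inherits(sp, "error")) {
    hf_v <- NA_real_; aci_v <- NA_real_; adi_v <- NA_real_
    aei_v <- NA_real_; ndsi_v <- NA_real_; bi_v <- NA_real_
  } else {
    aci_v <- safe(aci(sp)); hf_v <- safe(spectral_entropy(sp))
    adi_v <- safe(adi(sp)); aei_v <- safe(aei(sp))
    ndsi_v <- safe(ndsi(sp)); bi_v <- safe(bi(sp))
  }
  ht_v <- safe(temporal_entropy(x))
  ha_v <- if (is.na(hf_v) || is.na(ht_v)) NA_real_ else hf_v * ht_v
  data.frame(aci = aci_v, ha = ha_v, hf = hf_v, ht = ht_v, adi = adi_v,
             aei = aei_v, ndsi = ndsi_v, bi = bi_v)
}
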