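# shared fixtures, all generated in code

random_pmf <- function(M) {
  p <- stats::rexp(M)
  p / sum(p)
}

# synthetic spectrogram with a prescribed power matrix; bins spaced so that
# `bins_per_band` bins fall in each of the ten 0-10 kHz bands
make_spectrogram <- function(power, fmax = 10000, bands = 10, fs = 22050) {
  nb <- nrow(power)
  structure(
    list(power = power, f = seq(0.5, nb - 0.5) * (fmax / nb),
         t = seq_len(ncol(power)), fs = fs, nfft = 2 * nb, window = "hann"),
    class = "acoustic_spectrogram"
  )
}

# least-squares log-log PSD slope over [f_lo, f_hi], periodogram averaged
# over seeds: the independent oracle for the colored-noise generator
psd_slope <- function(alpha, seeds, n = 2^17, fs = 44100,
                      f_lo = 20, f_hi = 10000) {
  acc <- NULL
  for (s in seeds) {
    x <- colored_noise(n, alpha = alpha, fs = fs, seed = s)$samples
    p <- Mod(stats::fft(x))[2:(n / 2)]^2
    acc <- if (is.null(acc)) p else acc + p
  }
  f <- (1:(n / 2 - 1)) * fs / n
  sel <- f >= f_lo & f <= f_hi
  unname(stats::coef(stats::lm(log(acc[sel]) ~ log(f[sel])))[2])
}

# direct O(N tau) evaluation of the unbiased autocorrelation definition
acf_direct <- function(x, tau_max) {
  n <- length(x)
  m <- mean(x)
  s2 <- sum((x - m)^2) / (n - 1)
  vapply(0:(tau_max - 1), function(tau) {
    if (tau == 0) return(1)
    sum((x[1:(n - tau)] - m) * (x[(1 + tau):n] - m)) / ((n - tau) * s2)
  }, numeric(1))
}
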