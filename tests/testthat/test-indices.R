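test_that("spectrogram matches a direct STFT and localizes a tone", {
  fs <- 44100
  x <- synth_scene(list(scene_tone(1000)), duration_s = 0.5, fs = fs)
  sp <- acoustic_spectrogram(x)
  expect_identical(sp$nfft, 512)

  # direct frame-by-frame Hann-windowed FFT as the oracle
  w <- 0.5 - 0.5 * cos(2 * pi * (0:511) / 511)
  n_frames <- floor(length(x$samples) / 512)
  for (fr in c(1, 5, n_frames)) {
    seg <- x$samples[((fr - 1) * 512 + 1):(fr * 512)]
    want <- Mod(fft(seg * w))[1:256]^2
    expect_equal(sp$power[, fr], want, tolerance = 1e-8)
  }

  # single dominant bin per frame at 1 kHz
  peaks <- apply(sp$power, 2, which.max)
  expect_true(all(abs(sp$f[peaks] - 1000) < fs / 512))

  expect_error(acoustic_spectrogram(rnorm(100), fs = 8000), "shorter")
})

test_that("ACI measures rate of spectral change, scale-free", {
  flat <- make_spectrogram(matrix(1, nrow = 20, ncol = 8))
  expect_equal(aci(flat), 0)

  one_band <- make_spectrogram(rbind(c(1, 3, 1, 3), matrix(0, 19, 4)))
  expect_equal(aci(one_band), (2 + 2 + 2) / 8)  # 0.75, zero bands add 0

  x <- synth_scene(list(scene_pulses(10, 3000)), duration_s = 0.5, fs = 44100,
                   noise_alpha = 0, snr_db = 3, seed = 1)
  sp1 <- acoustic_spectrogram(x)
  y <- acoustic_signal(7.3 * x$samples, x$fs)
  expect_equal(aci(acoustic_spectrogram(y)), aci(sp1), tolerance = 1e-12)
})

test_that("spectral and temporal entropies separate noise from tones", {
  white <- colored_noise(2^16, 0, seed = 4)
  expect_gt(spectral_entropy(white), 0.98)
  expect_gt(temporal_entropy(white), 0.95)
  expect_gt(acoustic_entropy(white), 0.95)

  tone <- synth_scene(list(scene_tone(3531.4)), duration_s = 1, fs = 44100)
  expect_lt(spectral_entropy(tone), 0.3)      # single-bin concentration
  expect_gt(temporal_entropy(tone), 0.999)    # constant envelope

  click <- numeric(44100)
  click[1000:1044] <- sin(2 * pi * 3000 * (0:44) / 44100)
  expect_lt(temporal_entropy(click, fs = 44100), 0.5)

  # Ha = Hf x Ht, so Ht ~ 1 makes Ha track Hf
  expect_equal(acoustic_entropy(tone),
               spectral_entropy(tone) * temporal_entropy(tone))
  expect_error(temporal_entropy(rep(1, 1000), fs = 8000), "degenerate")
})

test_that("ADI and AEI hit their analytic fixed points", {
  equal_occ <- make_spectrogram(matrix(1, nrow = 200, ncol = 10))
  expect_equal(adi(equal_occ), log(10))       # uniform 10-band PMF, in nats
  expect_equal(aei(equal_occ), 0)

  # all occupancy in one of ten bands (rows 1..20 cover 0-1 kHz)
  pw <- matrix(0, nrow = 200, ncol = 10)
  pw[1:20, ] <- 1
  one_band <- make_spectrogram(pw)
  expect_equal(adi(one_band), 0)
  expect_equal(aei(one_band), 0.9)            # sample Gini of a degenerate 10-vector

  # permutation of bands leaves both unchanged
  pw2 <- matrix(0, nrow = 200, ncol = 10)
  pw2[61:80, ] <- 1                           # band 4 instead of band 1
  expect_equal(aei(make_spectrogram(pw2)), aei(one_band))
  expect_equal(adi(make_spectrogram(pw2)), adi(one_band))

  # fmax above Nyquist is rejected
  low_fs <- make_spectrogram(matrix(1, 200, 4), fs = 16000)
  expect_error(adi(low_fs), "Nyquist")

  # thresholding: cells 50 dB under full scale do not count
  pw3 <- matrix(1e-6, nrow = 200, ncol = 10)  # -60 dB relative to max
  pw3[1:20, ] <- 1
  expect_equal(aei(make_spectrogram(pw3)), 0.9)
})

test_that("NDSI is biophony-positive and symmetric", {
  fs <- 44100
  bio_tone <- synth_scene(list(scene_tone(3531.4)), duration_s = 1, fs = fs)
  expect_gt(ndsi(bio_tone), 0.99)             # no anthrophony -> +1

  anthro_tone <- synth_scene(list(scene_tone(516.8)), duration_s = 1, fs = fs)
  expect_lt(ndsi(anthro_tone), -0.99)

  both <- synth_scene(list(scene_tone(516.8), scene_tone(3531.4)),
                      duration_s = 1, fs = fs)
  expect_equal(ndsi(both), 0, tolerance = 0.02)
})

test_that("BI integrates in-band energy above the band floor", {
  flat <- make_spectrogram(matrix(1, nrow = 200, ncol = 10))
  expect_equal(bi(flat), 0)                   # flat dB curve minus its minimum

  base <- synth_scene(list(scene_tone(3000)), duration_s = 0.5, fs = 44100,
                      noise_alpha = 0, snr_db = 10, seed = 2)
  richer <- synth_scene(list(scene_tone(3000), scene_tone(5000, amplitude = 2)),
                        duration_s = 0.5, fs = 44100,
                        noise_alpha = 0, snr_db = 10, seed = 2)
  expect_gt(bi(richer), bi(base))
})

test_that("index_set computes all indices and records failures as NA", {
  x <- synth_scene(list(scene_tone(3000), scene_pulses(6, 5000)),
                   duration_s = 1, fs = 44100, noise_alpha = 0, snr_db = 6,
                   seed = 8)
  res <- index_set(x)
  expect_named(res, c("aci", "ha", "hf", "ht", "adi", "aei", "ndsi", "bi"))
  expect_true(all(!is.na(res)))
  expect_true(res$hf >= 0 && res$hf <= 1)
  expect_true(res$ht >= 0 && res$ht <= 1)
  expect_true(res$ha >= 0 && res$ha <= 1)
  expect_true(res$aei >= 0 && res$aei <= 1)
  expect_true(res$ndsi >= -1 && res$ndsi <= 1)
  expect_gte(res$aci, 0)
  expect_gte(res$adi, 0)
  expect_equal(res$ha, res$hf * res$ht)

  # constant signal: envelope-based entropies fail -> NA, never zero
  const <- acoustic_signal(rep(0.3, 44100), 44100)
  res2 <- index_set(const)
  expect_true(is.na(res2$ht))
  expect_true(is.na(res2$ha))
  expect_equal(res2$ndsi, -1)  # all energy at DC: pure anthrophony band
})

test_that("index ranges hold across random synthetic scenes", {
  set.seed(50)
  for (i in 1:25) {
    comps <- list()
    if (runif(1) < 0.8)
      comps <- c(comps, list(scene_tone(runif(1, 300, 9000),
                                        amplitude = runif(1, 0.2, 2))))
    if (runif(1) < 0.5)
      comps <- c(comps, list(scene_pulses(sample(2:12, 1),
                                          runif(1, 1000, 8000))))
    x <- synth_scene(comps, duration_s = 0.3, fs = 22050,
                     noise_alpha = runif(1, 0, 2), snr_db = runif(1, -10, 20),
                     seed = i)
    res <- index_set(x)
    expect_true(res$hf >= 0 && res$hf <= 1)
    expect_true(res$ht >= 0 && res$ht <= 1)
    expect_true(res$aei >= 0 && res$aei <= 1)
    expect_true(res$ndsi >= -1 && res$ndsi <= 1)
    expect_gte(res$aci, 0)
    expect_gte(res$adi, 0)
  }
})
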