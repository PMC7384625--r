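test_that("singular spectrum is a normalized nonnegative histogram", {
  expect_equal(singular_spectrum(diag(4)), rep(0.25, 4))

  eps <- 1e-3
  m <- matrix(c(1, 1 - eps, 1 - eps, 1), 2)
  expect_equal(singular_spectrum(m), c((2 - eps) / 2, eps / 2))

  set.seed(2)
  p <- singular_spectrum(acf_toeplitz(acf_unbiased(rnorm(2000), 64)))
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)

  expect_error(singular_spectrum(matrix(c(1, NA, NA, 1), 2)), "finite")
})

test_that("normalized entropy attains its analytic values", {
  for (M in c(2, 8, 512)) expect_equal(norm_entropy(rep(1 / M, M)), 1)
  expect_equal(norm_entropy(c(1, 0, 0, 0)), 0)
  # direct evaluation of -(0.75 log 0.75 + 0.25 log 0.25) / log 2
  expect_equal(norm_entropy(c(3 / 4, 1 / 4)), 0.8112781245, tolerance = 1e-9)
  expect_error(norm_entropy(c(1)), "length")
  expect_error(norm_entropy(c(0.7, 0.2)), "sum")
})

test_that("Jensen-Shannon divergence is symmetric, zero on identity", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_pmf(32); q <- random_pmf(32)
    expect_equal(jensen_shannon(p, q), jensen_shannon(q, p))
    expect_gte(jensen_shannon(p, q), 0)
    expect_equal(jensen_shannon(p, p), 0)
  }
  # midpoint of (1,0) and (1/2,1/2) is (3/4,1/4): J = H(3/4,1/4) - 1/2
  expect_equal(jensen_shannon(c(1, 0), c(0.5, 0.5)), 0.3112781245,
               tolerance = 1e-9)
  expect_error(jensen_shannon(c(1, 0), rep(1 / 3, 3)), "length")
})

test_that("Q0 is the reciprocal of the degenerate-vs-uniform divergence", {
  # dual route: closed form vs direct J evaluation
  expect_equal(q0(2), 1 / jensen_shannon(c(1, 0), c(0.5, 0.5)),
               tolerance = 1e-12)
  expect_equal(q0(2), 3.2125610, tolerance = 1e-6)
  for (M in c(2, 3, 16, 64, 257, 512, 1024)) {
    deg <- c(1, rep(0, M - 1))
    expect_equal(q0(M) * jensen_shannon(deg, rep(1 / M, M)), 1,
                 tolerance = 1e-12)
    expect_gt(q0(M), 0)
  }
  expect_error(q0(1), "M")
})

test_that("disequilibrium and complexity hit their fixed points", {
  for (M in c(2, 64, 512)) {
    unif <- rep(1 / M, M)
    deg <- c(1, rep(0, M - 1))
    expect_equal(disequilibrium(unif), 0)
    expect_equal(disequilibrium(deg), 1, tolerance = 1e-12)
    expect_equal(complexity(unif), 0)
    expect_equal(complexity(deg), 0)
  }
  # compose the three oracles on (3/4, 1/4)
  p <- c(3 / 4, 1 / 4)
  J <- jensen_shannon(p, c(0.5, 0.5))
  expect_equal(complexity(p), q0(2) * J * norm_entropy(p), tolerance = 1e-12)

  set.seed(21)
  qs <- replicate(1000, disequilibrium(random_pmf(64)))
  expect_true(all(qs >= 0 & qs <= 1))
})

test_that("complexity vanishes only at order or equilibrium", {
  set.seed(3)
  for (i in 1:50) {
    p <- random_pmf(16)
    H <- norm_entropy(p)
    J <- jensen_shannon(p, rep(1 / 16, 16))
    C <- complexity(p)
    if (H > 1e-6 && J > 1e-6) expect_gt(C, 0)
    expect_equal(C, q0(16) * J * H, tolerance = 1e-12)
  }
})

test_that("the EGCI pipeline maps canonical signals to expected regions", {
  white <- egci(colored_noise(2^16, alpha = 0, seed = 1), tau_max = 256)
  expect_gt(white$H, 0.95)     # disordered endpoint: H -> 1
  expect_lt(white$C, 0.05)

  tone <- egci(synth_scene(list(scene_tone(1000)), duration_s = 1.5,
                           fs = 44100), tau_max = 256)
  expect_lt(tone$H, white$H - 0.5)  # concentrated singular spectrum

  mix <- egci(synth_scene(list(scene_tone(1000), scene_pulses(8, 4000)),
                          duration_s = 1.5, fs = 44100,
                          noise_alpha = 0, snr_db = 0, seed = 9),
              tau_max = 256)
  expect_gt(mix$H, tone$H)
  expect_lt(mix$H, white$H)
  expect_gt(mix$C, tone$C)
  expect_gt(mix$C, white$C)
})

test_that("EGCI is invariant to affine rescaling of the waveform", {
  x <- synth_scene(list(scene_tone(800)), duration_s = 0.5, fs = 8000,
                   noise_alpha = 0, snr_db = 6, seed = 4)
  a <- egci(x, tau_max = 128)
  y <- acoustic_signal(-3.7 * x$samples + 0.25, x$fs)
  b <- egci(y, tau_max = 128)
  expect_equal(a$H, b$H, tolerance = 1e-10)
  expect_equal(a$C, b$C, tolerance = 1e-10)
})

test_that("SVD and symmetric-eigen routes agree on singular spectra", {
  set.seed(17)
  for (i in 1:10) {
    m <- acf_toeplitz(acf_unbiased(rnorm(3000), 64))
    sv <- singular_spectrum(m)
    ev <- abs(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    ev <- sort(ev, decreasing = TRUE); ev <- ev / sum(ev)
    expect_lt(max(abs(sv - ev)), 1e-10)
  }
})

test_that("egci_batch skips degenerate segments and keeps metadata", {
  segs <- list(
    colored_noise(4000, 0, fs = 4000, seed = 1),
    acoustic_signal(rep(0.5, 4000), 4000),   # constant: degenerate
    colored_noise(4000, 1, fs = 4000, seed = 2)
  )
  segs[[1]]$timestamp <- as.POSIXct("2016-07-01 05:00:00", tz = "UTC")
  segs[[3]]$timestamp <- as.POSIXct("2016-07-01 05:00:22", tz = "UTC")
  expect_warning(res <- egci_batch(segs, tau_max = 64), "degenerate")
  expect_identical(nrow(res), 2L)
  expect_identical(res$segment_index, c(1L, 3L))
  expect_true(all(res$H >= 0 & res$H <= 1))
})
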