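# Empirical mode decomposition, its ensemble variant, the Hilbert analytic
# signal, and the IMF-band denoiser.

test_that("EMD is complete and separates well-spaced tones", {
  t <- (0:1999) / 200
  x <- sin(2 * pi * 8 * t) + sin(2 * pi * 1 * t)
  dec <- emd(x)
  expect_lt(rel_l2_err(rowSums(dec$imfs) + dec$residue, x), 1e-8)
  expect_gt(abs(cor(dec$imfs[, 1], sin(2 * pi * 8 * t))), 0.95)

  # IMF admissibility: extrema and zero-crossing counts differ by <= 1
  for (j in seq_len(dec$n_imfs)) {
    imf <- dec$imfs[, j]
    n_ext <- length(pulsekit:::local_maxima(imf)) +
      length(pulsekit:::local_minima(imf))
    n_zc <- sum(diff(sign(imf[imf != 0])) != 0)
    expect_lte(abs(n_ext - n_zc), 2)
  }
})

test_that("monotone input yields zero IMFs with the input as residue", {
  ramp <- seq_len(100) / 3
  dec <- emd(ramp)
  expect_equal(dec$n_imfs, 0)
  expect_equal(dec$residue, ramp)
})

test_that("IMF mean frequencies decrease with index on multitone input", {
  t <- (0:1999) / 200
  x <- sin(2 * pi * 16 * t) + sin(2 * pi * 4 * t) + sin(2 * pi * 1 * t)
  dec <- emd(x)
  freqs <- vapply(seq_len(dec$n_imfs), function(j) {
    imf_mean_freq(dec$imfs[, j], 200)
  }, numeric(1))
  expect_true(all(diff(freqs) < 0))
})

test_that("EEMD is seeded-deterministic and approaches EMD for tiny noise", {
  t <- (0:799) / 200
  x <- sin(2 * pi * 6 * t) + 0.5 * sin(2 * pi * 1.5 * t)
  e1 <- eemd(x, ensemble_size = 10, noise_sd = 0.1 * sd(x), seed = 3)
  e2 <- eemd(x, ensemble_size = 10, noise_sd = 0.1 * sd(x), seed = 3)
  expect_identical(e1$imfs, e2$imfs)

  tiny <- eemd(x, ensemble_size = 2, noise_sd = 1e-12 * sd(x), seed = 1)
  plain <- emd(x)
  k <- min(tiny$n_imfs, plain$n_imfs)
  expect_lt(rel_l2_err(tiny$imfs[, 1:k], plain$imfs[, 1:k]), 1e-4)

  expect_error(eemd(x, noise_sd = 0), class = "pulsekit_bad_argument")
})

test_that("ensemble averaging reduces mode mixing from a transient", {
  t <- (0:1599) / 200
  low <- sin(2 * pi * 1.5 * t)
  x <- sin(2 * pi * 10 * t) + low
  x_step <- x + ifelse(t > 4 & t < 4.1, 1.5, 0)  # impulse-like perturbation
  plain <- emd(x_step)
  ens <- eemd(x_step, ensemble_size = 50, noise_sd = 0.2 * sd(x_step), seed = 2)
  mix_plain <- abs(cor(plain$imfs[, 1], low))
  mix_ens <- abs(cor(ens$imfs[, 1], low))
  expect_lt(mix_ens, mix_plain + 0.05)
  expect_lt(mix_ens, 0.2)
})

test_that("analytic signal reproduces known Hilbert pairs and frequencies", {
  t <- (0:1999) / 200
  a <- hilbert_analytic(cos(2 * pi * 5 * t), fs = 200)
  mid <- 101:1900
  expect_lt(max(abs(a$imag[mid] - sin(2 * pi * 5 * t)[mid])), 1e-2)
  expect_equal(median(a$inst_freq[mid]), 5, tolerance = 0.05)

  # linear chirp 1 -> 10 Hz over 10 s: instantaneous frequency 5.5 Hz at 5 s
  chirp <- cos(2 * pi * (t + 0.45 * t^2))
  ac <- hilbert_analytic(chirp, fs = 200)
  expect_equal(ac$inst_freq[1001], 5.5, tolerance = 0.2)

  const <- hilbert_analytic(rep(3, 64), fs = 200)
  expect_true(attr(const, "constant"))
  expect_equal(const$inst_freq, rep(0, 64))
})

test_that("IMF-band denoising keeps the pulse band and drops the rest", {
  t <- (0:1999) / 200
  x <- sin(2 * pi * 30 * t) + sin(2 * pi * 2 * t)
  y <- denoise_eemd(x, fs = 200, ensemble_size = 50, seed = 1)
  expect_lt(rel_l2_err(as.numeric(y), sin(2 * pi * 2 * t)), 0.15)
  rep <- attr(y, "eemd_report")
  expect_false(rep$kept[1])  # the 30 Hz mode is discarded

  inband <- sin(2 * pi * 5 * t)
  y2 <- denoise_eemd(inband, fs = 200, ensemble_size = 50, seed = 1)
  expect_lt(rel_l2_err(as.numeric(y2), inband), 0.1)

  expect_error(
    denoise_eemd(sin(2 * pi * 40 * t), fs = 200, ensemble_size = 10,
      seed = 1, low_cut = 39.9, high_cut = 39.95),
    class = "pulsekit_all_imfs_discarded"
  )
})

test_that("EEMD denoising removes drift from synthetic beats", {
  rec <- drift_record(duration = 10)
  base <- subtract_baseline(rec)
  y <- denoise_eemd(base, ensemble_size = 50, seed = 4)
  gt <- ground_truth(rec)
  amp <- diff(range(y$pressure))
  mins <- vapply(seq_len(nrow(gt) - 1), function(k) {
    min(y$pressure[gt$b[k]:gt$b[k + 1]])
  }, numeric(1))
  expect_lt(diff(range(mins)), 0.12 * amp)
})

test_that("wavelet and EEMD denoisers agree on the drift-contaminated record", {
  rec <- subtract_baseline(drift_record(duration = 10))
  yw <- denoise_wavelet(rec)
  ye <- denoise_eemd(rec, ensemble_size = 50, seed = 1)
  expect_lt(rel_l2_err(ye$pressure, yw$pressure), 0.2)
})
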