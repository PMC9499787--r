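# Dyadic wavelet machinery: level arithmetic, band bookkeeping, transform
# correctness against an independently computed reference, and the
# band-zeroing denoiser.

test_that("level arithmetic follows floor/ceil log2 rules", {
  expect_identical(max_level(1000), 9L)
  expect_identical(max_level(2), 1L)
  expect_identical(max_level(1024), 10L)
  expect_error(max_level(1), class = "pulsekit_bad_argument")

  expect_identical(single_cycle_level(1000, 7), 8L)
  expect_identical(single_cycle_level(1024, 1), 10L)
  expect_identical(single_cycle_level(1000, 10), 7L)
  expect_error(single_cycle_level(1000, 0), class = "pulsekit_bad_argument")
})

test_that("band edges reproduce the dyadic table at fs 200", {
  expect_equal(unname(band_edges(1, 200, "detail")), c(50, 100))
  expect_equal(unname(band_edges(5, 200, "detail")), c(3.125, 6.25))
  expect_equal(unname(band_edges(9, 200, "approx")), c(0, 0.1953125))
  expect_error(band_edges(2.5, 200), class = "pulsekit_bad_argument")

  tab <- band_table(9, 200)
  expect_equal(nrow(tab), 10)
  # printed to one decimal these are 50-100, 25-50, ..., 0.2-0.4, 0-0.2
  expect_equal(tab$high_hz[1:9], 100 / 2^(0:8))
  expect_equal(tab$low_hz[10], 0)
})

test_that("decomposition matches the PyWavelets reference coefficients", {
  ref <- jsonlite::read_json(test_path("pywt-dwt-fixture.json"),
    simplifyVector = TRUE)
  for (mode in c("per", "sym")) {
    b <- if (mode == "per") "periodic" else "symmetric"
    d1 <- wavelet_decompose(ref[[mode]]$x_even, levels = 1, boundary = b)
    expect_equal(d1$approx, ref[[mode]]$cA_even, tolerance = 1e-12)
    expect_equal(d1$details$cD1, ref[[mode]]$cD_even, tolerance = 1e-12)

    d3 <- wavelet_decompose(ref[[mode]]$x_odd, levels = 3, boundary = b)
    expect_equal(d3$approx, ref[[mode]]$wavedec3$cA3, tolerance = 1e-12)
    expect_equal(d3$details$cD3, ref[[mode]]$wavedec3$cD3, tolerance = 1e-12)
    expect_equal(d3$details$cD2, ref[[mode]]$wavedec3$cD2, tolerance = 1e-12)
    expect_equal(d3$details$cD1, ref[[mode]]$wavedec3$cD1, tolerance = 1e-12)
  }
})

test_that("reconstruction is exact for random signals of awkward lengths", {
  set.seed(7)
  for (L in c(37, 256, 1000, 1013)) {
    x <- rnorm(L)
    for (b in c("periodic", "symmetric")) {
      d <- wavelet_decompose(x, levels = max_level(L), boundary = b)
      expect_lt(rel_l2_err(wavelet_reconstruct(d), x), 1e-8)
    }
  }
})

test_that("the periodic transform is orthogonal on fully even cascades", {
  set.seed(8)
  x <- rnorm(1024)
  d <- wavelet_decompose(x, levels = 10)
  coef_energy <- sum(d$approx^2) +
    sum(vapply(d$details, function(v) sum(v^2), numeric(1)))
  expect_equal(coef_energy, sum(x^2), tolerance = 1e-12)
})

test_that("beat counting finds the dominant rate and ignores drift", {
  t7 <- (0:1399) / 200
  expect_identical(count_beats(sin(2 * pi * t7), fs = 200), 7L)

  rec <- clean_record()
  expect_equal(count_beats(rec), nrow(ground_truth(rec)), tolerance = 1)

  drifted <- drift_record()
  expect_identical(count_beats(drifted), count_beats(rec))

  expect_error(count_beats(sin(2 * pi * t7[1:300]), fs = 200),
    class = "pulsekit_bad_argument")
})

test_that("the canonical configuration zeroes cD1, cD2, cD8, cD9, cA9", {
  t <- (0:999) / 200
  x <- sin(2 * pi * 1.2 * t)
  y <- denoise_wavelet(x, fs = 200, beats = 7)
  expect_setequal(attr(y, "denoise_report")$zeroed,
    c("cD1", "cD2", "cD8", "cD9", "cA9"))
  expect_equal(attr(y, "denoise_report")$levels, 9)
  expect_equal(attr(y, "denoise_report")$single_cycle_level, 8)
})

test_that("denoiser attenuation matches the independent reference values", {
  # expected values computed with PyWavelets running the identical zeroing
  # scheme (db7, L = 1000, fs = 200, M = 7), in both boundary modes
  t <- (0:999) / 200
  tone30 <- sin(2 * pi * 30 * t)
  expect_equal(
    sqrt(sum(denoise_wavelet(tone30, fs = 200, beats = 7,
      boundary = "periodic")^2) / sum(tone30^2)),
    0.34796253918,
    tolerance = 1e-8
  )
  expect_equal(
    sqrt(sum(denoise_wavelet(tone30, fs = 200, beats = 7,
      boundary = "symmetric")^2) / sum(tone30^2)),
    0.356479125704504,
    tolerance = 1e-10
  )
  drift <- sin(2 * pi * 0.1 * t)
  expect_equal(
    sqrt(sum(denoise_wavelet(drift, fs = 200, beats = 7,
      boundary = "periodic")^2) / sum(drift^2)),
    0.01492746672,
    tolerance = 1e-8
  )
  # band-limited beat surrogate passes nearly unchanged (< 5%)
  band <- sin(2 * pi * 1.2 * t) + 0.5 * sin(2 * pi * 3 * t)
  expect_equal(
    rel_l2_err(as.numeric(denoise_wavelet(band, fs = 200, beats = 7,
      boundary = "periodic")), band),
    0.04678127795,
    tolerance = 1e-8
  )
  expect_lt(
    rel_l2_err(as.numeric(denoise_wavelet(band, fs = 200, beats = 7,
      boundary = "periodic")), band),
    0.05
  )
  # a tone well inside the zeroed cD2 band is strongly attenuated
  tone40 <- sin(2 * pi * 40 * t)
  expect_lt(sqrt(sum(denoise_wavelet(tone40, fs = 200, beats = 7,
    boundary = "periodic")^2) / sum(tone40^2)), 0.05)
})

test_that("band zeroing is an orthogonal projection (idempotent)", {
  # fully even cascade: the projection is exact
  set.seed(13)
  x24 <- rnorm(1024)
  y1 <- as.numeric(denoise_wavelet(x24, fs = 204.8, beats = 7,
    boundary = "periodic"))
  y2 <- as.numeric(denoise_wavelet(y1, fs = 204.8, beats = 7,
    boundary = "periodic"))
  expect_lt(rel_l2_err(y2, y1), 1e-10)

  # odd intermediate lengths add one padding coefficient per odd level;
  # the residual energy a second pass removes stays below 1e-6 of total
  # (5.12 s at 200 Hz keeps the cascade even)
  rec <- drift_record(duration = 5.12)
  x <- rec$pressure - mean(rec$pressure)
  M <- count_beats(x, 200)
  z1 <- as.numeric(denoise_wavelet(x, fs = 200, beats = M,
    boundary = "periodic"))
  z2 <- as.numeric(denoise_wavelet(z1, fs = 200, beats = M,
    boundary = "periodic"))
  expect_lt(sum((z2 - z1)^2) / sum(z1^2), 1e-6)
})
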