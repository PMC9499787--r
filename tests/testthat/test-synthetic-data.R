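# Synthetic pulse generator: template invariants and separability, record
# determinism, ground-truth geometry, and the spectral compactness of
# clean beats.

test_that("templates are deterministic, validated and class-checked", {
  t1 <- make_template("Pingmai", 0)
  t2 <- make_template("Pingmai", 0)
  expect_identical(t1, t2)
  expect_equal(t1$beat_period, 0.8, tolerance = 0.1)
  expect_identical(t1$components$wave, c("c", "e", "g"))
  expect_error(make_template("Foomai"), class = "pulsekit_unknown_class")
  expect_error(make_template("Foomai"), "Valid classes")

  for (cls in mai_classes()) {
    tp <- make_template(cls, 5)
    amps <- tp$components$amplitude
    expect_gt(amps[1], amps[2])
    expect_gt(amps[1], amps[3])
    expect_true(!is.unsorted(tp$components$time_frac, strictly = TRUE))
  }
})

test_that("the ten default templates are pairwise distinguishable", {
  # noiseless beats on a common 1.3 s grid, amplitude-normalized; every
  # pair differs by the documented margin of 8% in relative L2 (the closest
  # pairs — the strong/normal/faint caricatures — additionally differ in
  # beat period and absolute amplitude)
  grid <- seq(0, 1.3, by = 1 / 200)
  shapes <- sapply(mai_classes(), function(cls) {
    tp <- make_template(cls, 0)
    p <- pulsekit:::eval_beat_train(tp, pmin(grid, tp$beat_period), 0)
    p / max(p)
  })
  for (i in 1:9) {
    for (j in (i + 1):10) {
      d <- sqrt(sum((shapes[, i] - shapes[, j])^2)) /
        max(sqrt(sum(shapes[, i]^2)), sqrt(sum(shapes[, j]^2)))
      expect_gt(d, 0.08)
    }
  }
})

test_that("records are bitwise deterministic and respect the noise model", {
  tpl <- make_template("Pingmai", 0)
  r1 <- synthesize_record(tpl, 6, 200, noise_spec(), seed = 4)
  r2 <- synthesize_record(tpl, 6, 200, noise_spec(), seed = 4)
  expect_identical(r1$pressure, r2$pressure)
  expect_identical(r1$time, r2$time)

  clean <- synthesize_record(tpl, 6, 200, zero_noise(), seed = 4)
  expect_identical(clean$time, (0:(6 * 200 - 1)) / 200)
  # zero-noise maximum = baseline + tallest point of the beat waveform
  beat_max <- max(pulsekit:::eval_beat_train(tpl,
    seq(0, tpl$beat_period, by = 1 / 2000), 0))
  expect_equal(max(clean$pressure) - tpl$baseline_pressure, beat_max,
    tolerance = 0.01 * beat_max)

  expect_error(synthesize_record(tpl, 1, 200, zero_noise()),
    class = "pulsekit_duration_too_short")
})

test_that("baseline drift moves per-beat minima off a horizontal line", {
  rec <- synthesize_record(make_template("Pingmai", 0), 12, 200,
    noise_spec(
      drift_amplitude = 300, drift_frequency = 0.1,
      hf_amplitude = 0, white_sd = 0, timestamp_jitter_sd = 0
    ),
    seed = 2)
  gt <- ground_truth(rec)
  beat_minima <- vapply(seq_len(nrow(gt) - 1), function(k) {
    min(rec$pressure[gt$b[k]:gt$b[k + 1]])
  }, numeric(1))
  expect_gt(diff(range(beat_minima)), 100)

  clean <- clean_record()
  gt0 <- ground_truth(clean)
  mins0 <- vapply(seq_len(nrow(gt0) - 1), function(k) {
    min(clean$pressure[gt0$b[k]:gt0$b[k + 1]])
  }, numeric(1))
  expect_lt(diff(range(mins0)), 5)
})

test_that("ground truth is ordered and b sits at the per-beat minimum", {
  for (cls in c("Pingmai", "Huamai", "Jimai")) {
    rec <- clean_record(cls, seed = 3)
    gt <- ground_truth(rec)
    expect_gt(nrow(gt), 5)
    idx <- c(t(as.matrix(gt[, c("b", "c", "e", "f", "g")])))
    expect_true(all(diff(idx[!is.na(idx)]) > 0))
    # b is the deepest point of each inter-main-wave valley
    for (k in 2:nrow(gt)) {
      seg <- gt$c[k - 1]:gt$c[k]
      expect_lte(abs(seg[which.min(rec$pressure[seg])] - gt$b[k]), 1)
    }
  }
})

test_that("clean pulse energy above 20 Hz is under 1% of the total", {
  rec <- clean_record()
  x <- rec$pressure - mean(rec$pressure)
  spec <- Mod(fft(x))^2
  freqs <- (seq_along(x) - 1) / length(x) * 200
  hf <- freqs > 20 & freqs < 180
  expect_lt(sum(spec[hf]) / sum(spec), 0.01)
})

test_that("make_dataset returns the requested per-class records", {
  ds <- make_dataset(c(Pingmai = 2, Jimai = 1), duration = 4,
    noise = zero_noise(), seed = 9)
  expect_equal(nrow(ds), 3)
  expect_equal(sum(ds$label == "Pingmai"), 2)
  ds2 <- make_dataset(c(Pingmai = 2, Jimai = 1), duration = 4,
    noise = zero_noise(), seed = 9)
  expect_identical(ds$record, ds2$record)

  expect_error(make_dataset(c()), class = "pulsekit_bad_argument")
  expect_error(make_dataset(c(Pingmai = 0)), class = "pulsekit_bad_argument")
  expect_error(make_dataset(c(Nomai = 2)), class = "pulsekit_unknown_class")
})
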