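# Differential-threshold fiducial detection: differentials, parameter
# validation, detector-vs-ground-truth agreement, and the structural
# invariants (ordering, scale invariance, b/c pairing).

test_that("differentials are exact on polynomials and accurate on sines", {
  d <- differentiate(3 * (0:20), fs = 1)
  expect_equal(d$first, rep(3, 21))
  expect_equal(d$second, rep(0, 21))

  d2 <- differentiate((0:10)^2, fs = 1)
  expect_equal(d2$second, rep(2, 11))

  t <- (0:999) / 200
  ds <- differentiate(sin(2 * pi * t), fs = 200)
  expect_lt(max(abs(ds$first - 2 * pi * cos(2 * pi * t))[10:990]), 1e-2)

  expect_error(differentiate(c(1, 2)), class = "pulsekit_bad_argument")
})

test_that("threshold parameters are validated", {
  p <- threshold_params()
  expect_equal(p$m, 0.7)
  expect_error(threshold_params(m = 1.01), class = "pulsekit_bad_argument")
  expect_error(threshold_params(n = 0.8, m = 0.7),
    class = "pulsekit_bad_argument")
  expect_error(threshold_params(k = 0), class = "pulsekit_bad_argument")
})

test_that("detector recovers ground truth on clean records of every class", {
  for (cls in mai_classes()) {
    rec <- clean_record(cls, seed = 11)
    gt <- ground_truth(rec)
    det <- detect_fiducials(subtract_baseline(rec))
    expect_equal(nrow(det), nrow(gt))
    for (p in c("b", "c", "e", "f", "g")) {
      expect_true(all(!is.na(det[[p]])), info = paste(cls, p))
      expect_lte(max(abs(det[[p]] - gt[[p]])), 3)
    }
  }
})

test_that("ordering b < c < e < f < g holds in every returned beat", {
  det <- detect_fiducials(subtract_baseline(clean_record("Shimai", 2)))
  for (i in seq_len(nrow(det))) {
    idx <- unlist(det[i, c("b", "c", "e", "f", "g")])
    expect_true(all(diff(idx[!is.na(idx)]) > 0))
  }
  expect_equal(sum(!is.na(det$b)), sum(!is.na(det$c)))
})

test_that("detections are invariant to positive amplitude scaling", {
  rec <- subtract_baseline(clean_record("Huanmai", 7))
  det1 <- detect_fiducials(rec)
  rec$pressure <- rec$pressure * 417.3
  det2 <- detect_fiducials(rec)
  expect_identical(
    as.data.frame(det1[c("b", "c", "e", "f", "g")]),
    as.data.frame(det2[c("b", "c", "e", "f", "g")])
  )
})

test_that("a single symmetric bump gives one main wave at the apex", {
  t <- (0:999) / 200
  x <- exp(-(t - 2.5)^2 / (2 * 0.15^2))
  det <- detect_fiducials(x, fs = 200)
  expect_equal(nrow(det), 1)
  expect_equal(det$c[1], which.max(x))
  expect_equal(det$b[1], which.min(x[1:det$c[1]]))
})

test_that("an impossible main-wave threshold raises a clear error", {
  rec <- subtract_baseline(clean_record())
  expect_error(
    detect_fiducials(rec, params = threshold_params(m = 1)),
    class = "pulsekit_no_main_wave"
  )
  expect_error(
    detect_fiducials(rec, params = threshold_params(m = 1)),
    "no main wave",
    ignore.case = TRUE
  )
})
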