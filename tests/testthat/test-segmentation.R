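# Densification/resampling, onset-anchored segmentation with
# cross-interception augmentation, and the 7:3 split.

test_that("resampling through spline knots reproduces uniform input", {
  t <- (0:299) / 50
  rec <- tibble::tibble(time = t, pressure = sin(2 * pi * 1.1 * t))
  out <- densify_resample(rec, out_fs = 50)
  expect_equal(diff(out$time), rep(1 / 50, nrow(out) - 1), tolerance = 1e-12)
  shared <- seq_len(min(nrow(out), nrow(rec)))
  expect_lt(max(abs(out$pressure[shared] - rec$pressure[shared])), 1e-9)
})

test_that("jittered sampling of a sine resamples to the analytic curve", {
  set.seed(5)
  t <- sort((0:2399) / 200 + rnorm(2400, 0, 4e-4))
  t <- t - t[1]
  rec <- tibble::tibble(time = t, pressure = sin(2 * pi * t))
  out <- densify_resample(rec, factor = 10, out_fs = 50)
  interior <- out$time > 0.2 & out$time < max(out$time) - 0.2
  expect_lt(max(abs(out$pressure - sin(2 * pi * out$time))[interior]), 1e-3)
})

test_that("a 12 s record yields 600 +/- 1 samples at 50 Hz", {
  rec <- clean_record(duration = 12)
  out <- densify_resample(rec)
  expect_lte(abs(nrow(out) - 600), 1)
  dup <- rec
  dup$time[5] <- dup$time[4]  # duplicate timestamps violate monotonicity
  expect_error(densify_resample(dup), class = "pulsekit_nonmonotone_time")
})

test_that("segment counting matches the cross-interception rule", {
  series <- sin(2 * pi * (0:599) / 40)
  onsets <- seq(11, 571, by = 40)  # 15 onsets, 0.8 s apart at 50 Hz
  segs <- segment_at_onsets(series, onsets, length = 300, scale = FALSE)
  expect_equal(nrow(segs), sum(onsets + 299 <= 600))
  expect_equal(nrow(segs), 8)
  expect_true(all(lengths(segs$values) == 300))
  # each segment is a contiguous slice of the input
  for (i in seq_len(nrow(segs))) {
    expect_identical(segs$values[[i]],
      series[segs$onset[i]:(segs$onset[i] + 299)])
  }

  expect_warning(short <- segment_at_onsets(series[1:200], c(1, 50)),
    "full segment")
  expect_equal(nrow(short), 0)

  one <- segment_at_onsets(series[1:300], 1, scale = FALSE)
  expect_equal(nrow(one), 1)
  expect_identical(one$values[[1]], series[1:300])
})

test_that("min-max scaling maps each segment to [0, 1]", {
  series <- 500 + 300 * sin(2 * pi * (0:599) / 40)
  segs <- segment_at_onsets(series, c(1, 41, 81), length = 300)
  for (v in segs$values) {
    expect_equal(range(v), c(0, 1))
  }
})

make_fake_segments <- function(n, label = "Pingmai", source = "src") {
  out <- tibble::tibble(
    segment_id = sprintf("%s#%04d", source, seq_len(n)),
    source_id = rep(source, n),
    label = rep(label, n),
    onset = seq_len(n),
    values = lapply(seq_len(n), function(i) runif(300))
  )
  class(out) <- c("segment_set", class(out))
  attr(out, "segment_length") <- 300L
  out
}

test_that("677 segments split 7:3 into exactly 473 and 204", {
  set.seed(1)
  segs <- make_fake_segments(677)
  sp <- split_segments(segs, seed = 42)
  expect_equal(nrow(sp$train), 473)
  expect_equal(nrow(sp$test), 204)
  expect_length(intersect(sp$train$segment_id, sp$test$segment_id), 0)

  sp10 <- split_segments(make_fake_segments(10), seed = 1)
  expect_equal(c(nrow(sp10$train), nrow(sp10$test)), c(7, 3))

  sp2 <- split_segments(segs, seed = 42)
  expect_identical(sp$train$segment_id, sp2$train$segment_id)

  expect_error(split_segments(make_fake_segments(5)),
    class = "pulsekit_bad_argument")
  expect_error(split_segments(segs, ratio = c(7, -1)),
    class = "pulsekit_bad_argument")
})

test_that("grouped splitting keeps each source on one side", {
  set.seed(2)
  segs <- dplyr::bind_rows(lapply(1:12, function(i) {
    make_fake_segments(6, source = paste0("rec", i))
  }))
  class(segs) <- c("segment_set", class(segs))
  attr(segs, "segment_length") <- 300L
  sp <- split_segments(segs, seed = 3, group_by_record = TRUE)
  expect_length(intersect(unique(sp$train$source_id),
    unique(sp$test$source_id)), 0)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(segs))
})
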