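# CNN architecture arithmetic, layer correctness (gradients against finite
# differences on a shrunken clone), dropout behaviour, training
# reproducibility, and the evaluation metrics.

test_that("shape trace reproduces the fixed architecture", {
  tr <- shape_trace(cnn_config())
  expect_equal(tr$length, c(300, 291, 282, 94, 85, 76, 1, 1, 1))
  expect_equal(tr$channels, c(1, 100, 100, 100, 160, 160, 160, 160, 10))
  expect_equal(unlist(tr[tr$layer == "conv1", c("length", "channels")]),
    c(length = 291, channels = 100))
  expect_equal(unlist(tr[tr$layer == "conv4", c("length", "channels")]),
    c(length = 76, channels = 160))

  tiny <- shape_trace(cnn_config(input_length = 120))
  expect_equal(tiny$length[2], 111)
  expect_error(shape_trace(cnn_config(input_length = 40)),
    class = "pulsekit_bad_shape")  # the third convolution collapses
})

test_that("backpropagation matches finite differences on a shrunken net", {
  cfg <- cnn_config(input_length = 80, n_classes = 3)
  cfg$conv_filters <- c(4L, 5L, 6L, 7L)
  set.seed(42)
  params <- pulsekit:::init_params(cfg)
  X <- matrix(rnorm(3 * 80), 3)
  y1h <- diag(3)[c(1, 3, 2), ]
  loss_fn <- function(p) {
    -mean(log(rowSums(pulsekit:::cnn_forward(p, X, cfg)$probs * y1h)))
  }
  fw <- pulsekit:::cnn_forward(params, X, cfg, keep = TRUE)
  grads <- pulsekit:::cnn_backward(params, fw, y1h, cfg)
  eps <- 1e-6
  for (nm in names(grads)) {
    for (i in sample(length(params[[nm]]), min(5, length(params[[nm]])))) {
      pp <- params
      pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params
      pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("softmax outputs are probabilities summing to one", {
  cfg <- cnn_config()
  set.seed(1)
  params <- pulsekit:::init_params(cfg)
  X <- matrix(runif(4 * 300), 4)
  probs <- pulsekit:::cnn_forward(params, X, cfg)$probs
  expect_equal(unname(rowSums(probs)), rep(1, 4), tolerance = 1e-6)
  expect_true(all(probs >= 0))
})

test_that("dropout zeroes about half the units in training, none at inference", {
  set.seed(9)
  x <- matrix(1, 100, 100)
  dropped <- cnn_dropout(x, rate = 0.5, training = TRUE)
  frac <- mean(dropped == 0)
  expect_lt(abs(frac - 0.5), 0.05)
  expect_equal(unique(dropped[dropped != 0]), 2)  # inverted scaling 1/(1-p)
  expect_identical(cnn_dropout(x, rate = 0.5, training = FALSE), x)
})

test_that("training is reproducible and fits a degenerate task instantly", {
  segs <- tibble::tibble(
    segment_id = sprintf("s%02d", 1:12), source_id = "s",
    label = rep(c("Pingmai", "Jimai"), 6), onset = 1:12,
    values = lapply(1:12, function(i) {
      as.numeric(stats::filter(runif(300), rep(0.2, 5), circular = TRUE)) +
        (i %% 2)
    })
  )
  class(segs) <- c("segment_set", class(segs))
  attr(segs, "segment_length") <- 300L

  set.seed(77)
  m1 <- train_cnn(segs, cnn_config(epochs = 2), seed = 5)
  m2 <- train_cnn(segs, cnn_config(epochs = 2), seed = 5)
  expect_identical(m1$history$loss[1], m2$history$loss[1])
  expect_identical(m1$params, m2$params)

  one <- segs
  one$label <- rep("Pingmai", 12)
  m3 <- train_cnn(one, cnn_config(epochs = 5, n_classes = 1), seed = 1,
    classes = "Pingmai")
  expect_equal(max(m3$history$accuracy[1:5]), 1)
  expect_equal(m3$final_train_accuracy, 1)

  bad <- segs
  bad$label[1] <- "Nomai"
  expect_error(train_cnn(bad, cnn_config(epochs = 1), seed = 1),
    class = "pulsekit_unknown_class")
})

test_that("evaluation metrics follow the precision/recall/F1 definitions", {
  cm <- matrix(c(8, 2, 2, 8), 2, dimnames = list(c("A", "B"), c("A", "B")))
  m <- metrics_from_confusion(cm)
  expect_equal(m$precision, c(0.8, 0.8))
  expect_equal(m$recall, c(0.8, 0.8))
  expect_equal(m$f1, c(0.8, 0.8))

  # class with no true examples: undefined, not zero
  cm2 <- matrix(c(5, 0, 0, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  m2 <- metrics_from_confusion(cm2)
  expect_false(m2$present[2])
  expect_true(is.na(m2$recall[2]))
})

test_that("a perfect classifier scores 1 everywhere with a diagonal matrix", {
  segs <- tibble::tibble(
    segment_id = sprintf("t%02d", 1:20), source_id = "t",
    label = rep(c("Pingmai", "Jimai"), each = 10), onset = 1:20,
    values = lapply(1:20, function(i) {
      base <- if (i <= 10) sin(2 * pi * (1:300) / 40) else
        sin(2 * pi * (1:300) / 90)
      (base - min(base)) / diff(range(base))
    })
  )
  class(segs) <- c("segment_set", class(segs))
  attr(segs, "segment_length") <- 300L
  model <- train_cnn(segs, cnn_config(epochs = 15, n_classes = 2), seed = 2,
    classes = c("Pingmai", "Jimai"))
  rep <- evaluate_cnn(model, segs)
  expect_equal(rep$accuracy, 1)
  expect_equal(sum(rep$confusion) , 20)
  expect_true(all(diag(rep$confusion) == c(10, 10)))
  expect_equal(rep$macro_f1, 1)
  # metrics recomputed from the stored confusion equal the reported ones
  again <- metrics_from_confusion(rep$confusion)
  expect_equal(again$f1, rep$metrics$f1)
  expect_equal(glance(rep)$accuracy, 1)
  expect_equal(nrow(tidy(rep)), 2)
})
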