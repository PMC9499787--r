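# Fixed-architecture 1-D convolutional classifier:
#   conv(100 filters, kernel 10) x2 -> maxpool(3) ->
#   conv(160, kernel 10) x2 -> global average pool -> dropout(0.5) ->
#   dense(n_classes, softmax), categorical cross-entropy.
# Valid (no-padding) convolutions give the layer trace
#   300x1 -> 291x100 -> 282x100 -> 94x100 -> 85x160 -> 76x160 -> 1x160 -> 10.
# Implementation: im2col + BLAS matrix products, ReLU hidden activations,
# inverted dropout, Adam. Batch activations are stored as (batch*length x
# channels) matrices so every heavy step is a single gemm.

#' Configuration of the 1-D CNN pulse classifier
#'
#' The layer structure is fixed (two 100-filter convolutions, width-3 max
#' pooling, two 160-filter convolutions, global average pooling, dropout
#' 0.5, softmax head); training hyper-parameters are adjustable.
#'
#' @param input_length Samples per segment (default 300).
#' @param n_classes Number of output classes (default 10).
#' @param epochs Training epochs (default 50).
#' @param batch_size Minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-3).
#' @param dropout_rate Dropout probability before the head (default 0.5).
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(input_length = 300, n_classes = 10, epochs = 50,
                       batch_size = 32, learning_rate = 1e-3,
                       dropout_rate = 0.5) {
  assert_scalar_number(input_length, "input_length", min = 20)
  assert_scalar_number(n_classes, "n_classes", min = 1)
  assert_scalar_number(epochs, "epochs", min = 1)
  structure(
    list(
      input_length = as.integer(input_length), input_channels = 1L,
      conv_filters = c(100L, 100L, 160L, 160L), kernel = 10L, pool_width = 3L,
      n_classes = as.integer(n_classes), dropout_rate = dropout_rate,
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate
    ),
    class = "cnn_config"
  )
}

#' Layer-by-layer output shapes of the CNN
#'
#' Pure shape arithmetic (no weights): a valid convolution maps length
#' `L` to `L - kernel + 1`, width-3 max pooling to `floor(L / 3)`, global
#' average pooling to 1. For the default configuration the trace is
#' 300x1, 291x100, 282x100, 94x100, 85x160, 76x160, 1x160, 1x160, 10.
#'
#' @param config A [cnn_config()].
#' @return A tibble with `layer`, `length`, `channels`.
#' @export
#' @examples
#' shape_trace(cnn_config())
shape_trace <- function(config = cnn_config()) {
  stopifnot(inherits(config, "cnn_config"))
  k <- config$kernel
  len <- config$input_length
  rows <- list(list(layer = "input", length = len, channels = config$input_channels))
  push <- function(layer, length, channels) {
    if (length <= 0) {
      abort_pulsekit(sprintf("Layer %s collapses to non-positive length.", layer),
        "pulsekit_bad_shape")
    }
    rows[[base::length(rows) + 1]] <<- list(layer = layer, length = length,
      channels = channels)
  }
  push("conv1", len <- len - k + 1, config$conv_filters[1])
  push("conv2", len <- len - k + 1, config$conv_filters[2])
  push("maxpool", len <- len %/% config$pool_width, config$conv_filters[2])
  push("conv3", len <- len - k + 1, config$conv_filters[3])
  push("conv4", len <- len - k + 1, config$conv_filters[4])
  push("global_avg_pool", len <- 1L, config$conv_filters[4])
  push("dropout", 1L, config$conv_filters[4])
  push("dense_softmax", 1L, config$n_classes)
  purrr::map_dfr(rows, as_tibble)
}

#' Inverted dropout
#'
#' In training mode each unit is zeroed independently with probability
#' `rate` and the survivors are scaled by `1/(1-rate)` so the expected
#' activation is unchanged; in inference mode the input passes through
#' untouched.
#'
#' @param x Numeric vector or matrix of activations.
#' @param rate Drop probability.
#' @param training Logical; apply dropout or pass through.
#' @return Same shape as `x`.
#' @export
cnn_dropout <- function(x, rate = 0.5, training = TRUE) {
  if (!training || rate == 0) return(x)
  mask <- runif(length(x)) >= rate
  out <- x * mask / (1 - rate)
  attributes(out) <- attributes(x)
  out
}

# ---- internal layer plumbing -----------------------------------------------

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

he_init <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
}

init_params <- function(config) {
  k <- config$kernel
  f <- config$conv_filters
  list(
    W1 = he_init(k * config$input_channels, f[1]), b1 = numeric(f[1]),
    W2 = he_init(k * f[1], f[2]), b2 = numeric(f[2]),
    W3 = he_init(k * f[2], f[3]), b3 = numeric(f[3]),
    W4 = he_init(k * f[3], f[4]), b4 = numeric(f[4]),
    W5 = he_init(f[4], config$n_classes), b5 = numeric(config$n_classes)
  )
}

# Forward pass over a batch. X: (B x input_length). Returns the softmax
# probabilities and, when `keep = TRUE`, every intermediate needed for the
# backward pass.
cnn_forward <- function(params, X, config, training = FALSE, keep = FALSE) {
  B <- nrow(X)
  k <- config$kernel
  tr <- shape_trace(config)
  L <- tr$length
  A0 <- matrix(as.vector(t(X)), ncol = 1)

  Z1 <- cpp_conv_forward(A0, params$W1, params$b1, B, L[1], k)
  A1 <- Z1 * (Z1 > 0)

  Z2 <- cpp_conv_forward(A1, params$W2, params$b2, B, L[2], k)
  A2 <- Z2 * (Z2 > 0)

  # width-3 / stride-3 max pooling over the length axis
  Lp <- L[4] * 3L
  p1 <- as.vector(outer(seq(1L, Lp, 3L), (seq_len(B) - 1L) * L[3], "+"))
  X1 <- A2[p1, , drop = FALSE]
  X2 <- A2[p1 + 1L, , drop = FALSE]
  X3 <- A2[p1 + 2L, , drop = FALSE]
  P <- pmax(X1, X2, X3)

  Z3 <- cpp_conv_forward(P, params$W3, params$b3, B, L[4], k)
  A3 <- Z3 * (Z3 > 0)

  Z4 <- cpp_conv_forward(A3, params$W4, params$b4, B, L[5], k)
  A4 <- Z4 * (Z4 > 0)

  gap_group <- rep(seq_len(B), each = nrow(A4) / B)
  G <- rowsum(A4, gap_group) / (nrow(A4) / B)

  if (training && config$dropout_rate > 0) {
    mask <- matrix(runif(length(G)) >= config$dropout_rate, nrow(G), ncol(G))
    H <- G * mask / (1 - config$dropout_rate)
  } else {
    mask <- NULL
    H <- G
  }

  logits <- add_bias(H %*% params$W5, params$b5)
  probs <- exp(logits - apply(logits, 1, max))
  probs <- probs / rowSums(probs)

  if (!keep) return(list(probs = probs))
  list(
    probs = probs, A0 = A0, Z1 = Z1, A1 = A1, Z2 = Z2,
    p1 = p1, X1 = X1, X2 = X2, X3 = X3, P = P, Z3 = Z3, A3 = A3, Z4 = Z4,
    H = H, mask = mask, B = B, L = L
  )
}

cnn_backward <- function(params, fw, y_onehot, config) {
  B <- fw$B
  k <- config$kernel
  dZ5 <- (fw$probs - y_onehot) / B
  g <- list()
  g$W5 <- crossprod(fw$H, dZ5)
  g$b5 <- colSums(dZ5)
  dH <- tcrossprod(dZ5, params$W5)
  dG <- if (!is.null(fw$mask)) dH * fw$mask / (1 - config$dropout_rate) else dH

  Lg <- fw$L[6]  # length entering global average pooling (conv4 output)
  dA4 <- dG[rep(seq_len(B), each = Lg), , drop = FALSE] / Lg
  dZ4 <- dA4 * (fw$Z4 > 0)
  bk4 <- cpp_conv_backward(fw$A3, dZ4, params$W4, B, fw$L[5], k, TRUE)
  g$W4 <- bk4$dW
  g$b4 <- as.numeric(bk4$db)
  dA3 <- bk4$dA

  dZ3 <- dA3 * (fw$Z3 > 0)
  bk3 <- cpp_conv_backward(fw$P, dZ3, params$W3, B, fw$L[4], k, TRUE)
  g$W3 <- bk3$dW
  g$b3 <- as.numeric(bk3$db)
  dP <- bk3$dA

  m1 <- (fw$X1 >= fw$X2) & (fw$X1 >= fw$X3)
  m2 <- (fw$X2 > fw$X1) & (fw$X2 >= fw$X3)
  m3 <- !(m1 | m2)
  dA2 <- matrix(0, B * fw$L[3], ncol(fw$Z2))
  dA2[fw$p1, ] <- dP * m1
  dA2[fw$p1 + 1L, ] <- dA2[fw$p1 + 1L, , drop = FALSE] + dP * m2
  dA2[fw$p1 + 2L, ] <- dA2[fw$p1 + 2L, , drop = FALSE] + dP * m3

  dZ2 <- dA2 * (fw$Z2 > 0)
  bk2 <- cpp_conv_backward(fw$A1, dZ2, params$W2, B, fw$L[2], k, TRUE)
  g$W2 <- bk2$dW
  g$b2 <- as.numeric(bk2$db)
  dA1 <- bk2$dA

  dZ1 <- dA1 * (fw$Z1 > 0)
  bk1 <- cpp_conv_backward(fw$A0, dZ1, params$W1, B, fw$L[1], k, FALSE)
  g$W1 <- bk1$dW
  g$b1 <- as.numeric(bk1$db)
  g
}

adam_update <- function(params, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- training and prediction -----------------------------------------------

#' Train the 1-D CNN pulse classifier
#'
#' Builds the fixed-architecture network and trains it with Adam on the
#' training half of a [split_segments()] result (or any `segment_set`).
#' Per-epoch cross-entropy loss and training accuracy (running average over
#' minibatches, dropout active) are recorded; the final training accuracy
#' is also evaluated in inference mode after the last epoch.
#'
#' @param split A `split_dataset` (its `train` part is used) or a
#'   `segment_set`.
#' @param config A [cnn_config()].
#' @param seed Integer seed for initialization, shuffling and dropout; the
#'   same seed reproduces the run exactly.
#' @param classes Class levels; defaults to [mai_classes()].
#' @param verbose Print one line per epoch.
#' @return A `pulse_cnn` model: parameters, config, class levels, `history`
#'   tibble, and `final_train_accuracy`.
#' @export
train_cnn <- function(split, config = cnn_config(), seed = 0L,
                      classes = NULL, verbose = FALSE) {
  train_set <- if (inherits(split, "split_dataset")) split$train else split
  if (!inherits(train_set, "segment_set") || nrow(train_set) == 0) {
    abort_pulsekit("`split` must be a non-empty split_dataset or segment_set.",
      "pulsekit_bad_argument")
  }
  classes <- classes %||% mai_classes()
  if (length(classes) != config$n_classes) {
    abort_pulsekit("`config$n_classes` must match the number of class levels.",
      "pulsekit_bad_argument")
  }
  bad <- setdiff(unique(train_set$label), classes)
  if (length(bad) > 0) {
    abort_pulsekit(paste0("Labels outside the class set: ",
      paste(bad, collapse = ", ")), "pulsekit_unknown_class")
  }
  X <- do.call(rbind, train_set$values)
  y <- match(train_set$label, classes)
  if (ncol(X) != config$input_length) {
    abort_pulsekit("Segment length does not match `config$input_length`.",
      "pulsekit_bad_argument")
  }
  nobs <- nrow(X)
  onehot <- matrix(0, nobs, config$n_classes)
  onehot[cbind(seq_len(nobs), y)] <- 1

  with_seed(derive_seed(seed, "cnn"), {
    init <- init_params(config)
    orders <- vapply(seq_len(config$epochs), function(e) sample(nobs),
      integer(nobs))
    dropu <- runif(config$epochs * nobs * config$conv_filters[4])
    fit <- cpp_train_cnn(
      X, y,
      config$kernel, config$conv_filters[1], config$conv_filters[2],
      config$conv_filters[3], config$conv_filters[4], config$pool_width,
      config$n_classes, config$epochs, config$batch_size,
      config$learning_rate, config$dropout_rate, init,
      matrix(orders, nrow = nobs), dropu
    )
    history <- tibble(
      epoch = seq_len(config$epochs),
      loss = as.numeric(fit$loss), accuracy = as.numeric(fit$accuracy)
    )
    if (verbose) {
      purrr::pwalk(history, function(epoch, loss, accuracy) {
        inform(sprintf("epoch %3d  loss %.4f  acc %.3f", epoch, loss, accuracy))
      })
    }
    model <- structure(
      list(
        params = fit$params, config = config, classes = classes,
        history = history, seed = as.integer(seed)
      ),
      class = "pulse_cnn"
    )
    model$final_train_accuracy <- mean(predict(model, X) == classes[y])
    model
  })
}

#' @export
print.pulse_cnn <- function(x, ...) {
  cat(sprintf(
    "<pulse_cnn> %d classes, %d epochs trained, final train accuracy %.3f\n",
    x$config$n_classes, nrow(x$history), x$final_train_accuracy
  ))
  invisible(x)
}

#' Predict pulse classes or probabilities
#'
#' @param object A `pulse_cnn`.
#' @param newdata A `segment_set` or a numeric matrix with one segment per
#'   row.
#' @param type `"class"` (default) or `"prob"`.
#' @param batch_size Forward-pass batch size.
#' @param ... Unused.
#' @return A character vector of classes, or a probability matrix with one
#'   column per class (rows sum to 1).
#' @export
predict.pulse_cnn <- function(object, newdata, type = c("class", "prob"),
                              batch_size = 64, ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "segment_set")) do.call(rbind, newdata$values)
    else as.matrix(newdata)
  probs <- matrix(0, nrow(X), object$config$n_classes)
  for (s in seq(1, nrow(X), by = batch_size)) {
    rows <- s:min(s + batch_size - 1, nrow(X))
    probs[rows, ] <- cnn_forward(object$params, X[rows, , drop = FALSE],
      object$config, training = FALSE)$probs
  }
  colnames(probs) <- object$classes
  if (type == "prob") probs else object$classes[max.col(probs)]
}
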