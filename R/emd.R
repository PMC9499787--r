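# Empirical mode decomposition and its ensemble variant. Sifting uses
# natural cubic-spline envelopes through the extrema, with the first/last
# two extrema mirrored across the signal ends to control edge swing; the
# stop rule is the standard normalized squared-difference (SD) criterion
# with a sift cap per IMF.

find_extrema <- function(x) {
  list(max = local_maxima(x), min = local_minima(x))
}

# Envelope through (idx, x[idx]) with mirrored boundary extrema.
envelope <- function(x, idx) {
  n <- length(x)
  k <- length(idx)
  pos <- idx
  val <- x[idx]
  if (k >= 2) {
    lpos <- 2 - rev(idx[1:min(2, k)])
    lval <- rev(val[1:min(2, k)])
    rpos <- 2 * n - rev(rev(idx)[1:min(2, k)])
    rval <- rev(rev(val)[1:min(2, k)])
    pos <- c(lpos, pos, rpos)
    val <- c(lval, val, rval)
    keep <- !duplicated(pos)
    pos <- pos[keep]
    val <- val[keep]
  }
  splinefun(pos, val, method = "natural")(seq_len(n))
}

sift_once <- function(h) {
  ex <- find_extrema(h)
  if (length(ex$max) < 2 || length(ex$min) < 2) return(NULL)
  upper <- envelope(h, ex$max)
  lower <- envelope(h, ex$min)
  h - (upper + lower) / 2
}

extract_imf <- function(h, tolerance, max_sifts) {
  for (s in seq_len(max_sifts)) {
    h_new <- sift_once(h)
    if (is.null(h_new)) return(if (s == 1) NULL else h)
    sd_crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
    h <- h_new
    if (sd_crit < tolerance) break
  }
  h
}

new_imf_set <- function(imfs, residue, method, ensemble_size = NULL,
                        noise_sd = NULL) {
  structure(
    list(
      imfs = imfs, residue = residue, method = method,
      n_imfs = ncol(imfs), ensemble_size = ensemble_size, noise_sd = noise_sd
    ),
    class = "imf_set"
  )
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf(
    "<imf_set> %s: %d IMFs + residue, %d samples\n",
    x$method, x$n_imfs, nrow(x$imfs)
  ))
  invisible(x)
}

#' @export
tidy.imf_set <- function(x, ...) {
  n <- nrow(x$imfs)
  comps <- c(
    purrr::imap(
      as.data.frame(x$imfs) |> stats::setNames(paste0("IMF", seq_len(x$n_imfs))),
      function(v, nm) tibble(component = nm, sample = seq_len(n), value = v)
    ),
    list(tibble(component = "residue", sample = seq_len(n), value = x$residue))
  )
  dplyr::bind_rows(comps)
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs), ordered
#' high-frequency first, plus a residue; the components sum back to the
#' input exactly (to numerical precision). A monotone input yields zero
#' IMFs with the input as residue.
#'
#' @param x Numeric signal (length >= 16, finite).
#' @param max_imfs Cap on the number of IMFs extracted.
#' @param sift_tolerance Normalized squared-difference stop threshold per
#'   sift (default 0.2).
#' @param max_sifts Cap on sifting iterations per IMF (default 10).
#' @return An `imf_set`: IMF matrix (columns = IMFs), `residue`, `method`.
#' @export
#' @examples
#' t <- (0:799) / 200
#' dec <- emd(sin(2 * pi * 8 * t) + sin(2 * pi * 1 * t))
#' dec$n_imfs
emd <- function(x, max_imfs = 12, sift_tolerance = 0.2, max_sifts = 10) {
  if (!is.numeric(x) || length(x) < 16 || any(!is.finite(x))) {
    abort_pulsekit("`x` must be a finite numeric signal of length >= 16.",
      "pulsekit_bad_argument")
  }
  residue <- as.numeric(x)
  imfs <- list()
  while (length(imfs) < max_imfs) {
    imf <- extract_imf(residue, sift_tolerance, max_sifts)
    if (is.null(imf)) break
    imfs[[length(imfs) + 1]] <- imf
    residue <- residue - imf
    ex <- find_extrema(residue)
    if (length(ex$max) + length(ex$min) < 3) break
  }
  mat <- if (length(imfs)) do.call(cbind, imfs) else matrix(numeric(0), length(x), 0)
  new_imf_set(mat, residue, "EMD")
}

#' Ensemble empirical mode decomposition
#'
#' Runs [emd()] on `ensemble_size` white-noise-perturbed copies of the
#' signal and averages the IMFs index-wise (trials with fewer IMFs are
#' padded with zero components), cancelling the added noise and suppressing
#' mode mixing.
#'
#' @inheritParams emd
#' @param ensemble_size Number of noise realizations M (>= 2; default 100).
#' @param noise_sd Standard deviation of the added white noise, in signal
#'   units (> 0; default 0.2 x sd(x)).
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @return An `imf_set` with `method = "EEMD"`.
#' @export
eemd <- function(x, ensemble_size = 100, noise_sd = 0.2 * sd(x), seed = 0L,
                 max_imfs = 12, sift_tolerance = 0.2, max_sifts = 10) {
  assert_scalar_number(ensemble_size, "ensemble_size", min = 2)
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    abort_pulsekit("`noise_sd` must be > 0; use emd() for the noise-free transform.",
      "pulsekit_bad_argument")
  }
  L <- length(x)
  noise <- with_seed(
    derive_seed(seed, "eemd"),
    matrix(rnorm(L * ensemble_size, 0, noise_sd), L, ensemble_size)
  )
  acc <- list()
  res_acc <- numeric(L)
  for (i in seq_len(ensemble_size)) {
    dec <- emd(x + noise[, i], max_imfs, sift_tolerance, max_sifts)
    for (j in seq_len(dec$n_imfs)) {
      if (length(acc) < j) acc[[j]] <- numeric(L)
      acc[[j]] <- acc[[j]] + dec$imfs[, j]
    }
    res_acc <- res_acc + dec$residue
  }
  mat <- if (length(acc)) do.call(cbind, acc) / ensemble_size else
    matrix(numeric(0), L, 0)
  new_imf_set(mat, res_acc / ensemble_size, "EEMD",
    ensemble_size = ensemble_size, noise_sd = noise_sd)
}
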