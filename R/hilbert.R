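# Hilbert analytic-signal construction (frequency-domain -j*sgn(f)
# multiplier), instantaneous frequency, and the IMF-band denoiser that keeps
# components whose amplitude-weighted mean instantaneous frequency lies in
# the pulse band (0.5-20 Hz by default).

#' Analytic signal via the Hilbert transform
#'
#' Builds the analytic signal `z = x + i*H(x)` with the FFT method (double
#' the positive frequencies, zero the negative ones), and derives the
#' instantaneous amplitude, unwrapped phase, and instantaneous frequency
#' (central differences of the phase).
#'
#' @param x Uniformly sampled numeric signal.
#' @param fs Sampling rate in Hz.
#' @return An `analytic_signal` tibble with columns `real`, `imag`,
#'   `amplitude`, `phase`, `inst_freq`; attribute `constant` flags a
#'   constant input (instantaneous frequency reported as 0).
#' @export
#' @examples
#' a <- hilbert_analytic(cos(2 * pi * 5 * (0:999) / 200), fs = 200)
#' median(a$inst_freq)
hilbert_analytic <- function(x, fs) {
  if (!is.numeric(x) || length(x) < 4 || any(!is.finite(x))) {
    abort_pulsekit("`x` must be a finite numeric signal of length >= 4.",
      "pulsekit_bad_argument")
  }
  assert_scalar_number(fs, "fs", min = 0, strict_min = TRUE)
  n <- length(x)
  constant <- sd(x) == 0

  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[2:(n / 2)] <- 2
    h[n / 2 + 1] <- 1
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(fft(x) * h, inverse = TRUE) / n

  amplitude <- Mod(z)
  phase <- signal::unwrap(Arg(z))
  inst_freq <- if (constant) {
    numeric(n)
  } else {
    d <- numeric(n)
    d[2:(n - 1)] <- (phase[3:n] - phase[1:(n - 2)]) / 2
    d[1] <- phase[2] - phase[1]
    d[n] <- phase[n] - phase[n - 1]
    d * fs / (2 * pi)
  }

  out <- tibble(
    real = Re(z), imag = Im(z), amplitude = amplitude,
    phase = phase, inst_freq = inst_freq
  )
  class(out) <- c("analytic_signal", class(out))
  attr(out, "fs") <- fs
  attr(out, "constant") <- constant
  out
}

#' Mean instantaneous frequency of a component
#'
#' Amplitude-weighted mean of the instantaneous frequency, trimming the
#' first and last 5% of samples to avoid Hilbert edge effects. This single
#' number summarizes an IMF for band-keeping decisions.
#'
#' @param x Numeric component (e.g. one IMF).
#' @param fs Sampling rate in Hz.
#' @param trim Edge fraction to discard on each side (default 0.05).
#' @return Mean frequency in Hz (0 for a constant component).
#' @export
imf_mean_freq <- function(x, fs, trim = 0.05) {
  a <- hilbert_analytic(x, fs)
  if (attr(a, "constant")) return(0)
  n <- nrow(a)
  keep <- seq.int(max(1, floor(n * trim)), min(n, ceiling(n * (1 - trim))))
  w <- a$amplitude[keep]
  if (sum(w) == 0) return(0)
  sum(w * a$inst_freq[keep]) / sum(w)
}

#' EEMD/Hilbert band denoiser
#'
#' Decomposes the signal with [eemd()], summarizes each IMF by its
#' amplitude-weighted mean instantaneous frequency, and reconstructs from
#' the IMFs whose mean frequency lies within `[low_cut, high_cut]`. IMFs
#' below `low_cut` (baseline drift) and above `high_cut` (high-frequency
#' noise) are discarded, as is the residue (slow trend).
#'
#' @param x A pulse record data frame or numeric signal.
#' @param fs Sampling rate in Hz (required for numeric input).
#' @param low_cut,high_cut Keep band in Hz (defaults 0.5 and 20).
#' @param ensemble_size,noise_sd,seed Passed to [eemd()]; `noise_sd`
#'   defaults to 0.2 x sd of the signal.
#' @return Same shape as the input, with an `eemd_report` attribute: a
#'   tibble of per-IMF mean frequency and keep decision.
#' @export
denoise_eemd <- function(x, fs = NULL, low_cut = 0.5, high_cut = 20,
                         ensemble_size = 100, noise_sd = NULL, seed = 0L) {
  sig <- resolve_signal(x, fs)
  noise_sd <- noise_sd %||% (0.2 * sd(sig$signal))
  dec <- eemd(sig$signal, ensemble_size = ensemble_size, noise_sd = noise_sd,
    seed = seed)
  if (dec$n_imfs == 0) {
    abort_pulsekit("EEMD produced no IMFs (monotone input?).", "pulsekit_no_imfs")
  }
  freqs <- vapply(seq_len(dec$n_imfs), function(j) {
    imf_mean_freq(dec$imfs[, j], sig$fs)
  }, numeric(1))
  keep <- freqs >= low_cut & freqs <= high_cut
  report <- tibble(
    imf = seq_len(dec$n_imfs), mean_freq_hz = freqs, kept = keep
  )
  if (!any(keep)) {
    abort_pulsekit(
      paste0(
        "All IMFs fall outside the keep band [", low_cut, ", ", high_cut,
        "] Hz. Mean frequencies: ", paste(signif(freqs, 3), collapse = ", "), "."
      ),
      "pulsekit_all_imfs_discarded"
    )
  }
  clean <- rowSums(dec$imfs[, keep, drop = FALSE])
  if (is.data.frame(x)) {
    out <- x
    out$pressure <- clean
    attr(out, "eemd_report") <- report
    out
  } else {
    structure(clean, eemd_report = report)
  }
}
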