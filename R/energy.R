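# Wavelet-energy features: per-subband sums of squared coefficients from a
# 5-level decomposition, normalized by the total energy. Energies are
# computed on the decimated coefficients as-is (no per-level rescaling), so
# values are comparable across signals of equal length only.

#' Wavelet energy feature vector
#'
#' Decomposes the signal to 5 levels and returns the energy (sum of squared
#' coefficients) of `cA5, cD5, cD4, cD3, cD2, cD1` together with the
#' energy shares normalized by the total. At fs = 200 Hz the six subbands
#' span 0-3.125, 3.125-6.25, 6.25-12.5, 12.5-25, 25-50 and 50-100 Hz; a
#' clean pulse concentrates over 99% of its energy below 6.25 Hz
#' (cA5 + cD5).
#'
#' @param x A pulse record data frame or numeric signal (length >= 32).
#' @param fs Sampling rate in Hz (required for numeric input).
#' @param wavelet Wavelet name (default `"db7"`).
#' @return An `energy_feature` tibble with one row per subband:
#'   `coefficient`, `low_hz`, `high_hz`, `energy` (Pa^2), `share`;
#'   attribute `total` holds the total energy.
#' @export
#' @examples
#' rec <- synthesize_record(make_template("Pingmai"), 6, noise = zero_noise())
#' wavelet_energy(subtract_baseline(rec))
wavelet_energy <- function(x, fs = NULL, wavelet = "db7") {
  sig <- resolve_signal(x, fs)
  if (length(sig$signal) < 32) {
    abort_pulsekit("Need at least 32 samples for a 5-level decomposition.",
      "pulsekit_bad_argument")
  }
  if (all(sig$signal == 0)) {
    abort_pulsekit("All-zero signal has no energy to distribute.",
      "pulsekit_zero_energy")
  }
  dec <- wavelet_decompose(sig$signal, levels = 5, wavelet = wavelet,
    fs = sig$fs, boundary = "periodic")
  raw <- c(
    sum(dec$approx^2),
    vapply(5:1, function(j) sum(dec$details[[j]]^2), numeric(1))
  )
  names(raw) <- c("cA5", paste0("cD", 5:1))
  total <- sum(raw)
  edges <- rbind(
    band_edges(5, sig$fs, "approx"),
    t(vapply(5:1, function(j) band_edges(j, sig$fs, "detail"), numeric(2)))
  )
  out <- tibble(
    coefficient = names(raw),
    low_hz = edges[, 1], high_hz = edges[, 2],
    energy = unname(raw), share = unname(raw) / total
  )
  class(out) <- c("energy_feature", class(out))
  attr(out, "total") <- total
  attr(out, "fs") <- sig$fs
  out
}

#' @export
print.energy_feature <- function(x, ...) {
  cat(sprintf("<energy_feature> total %.4g Pa^2\n", attr(x, "total")))
  NextMethod()
}
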