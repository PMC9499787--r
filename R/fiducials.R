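# Differential-threshold detection of the five pulse fiducial points:
# onset valley (b), main-wave peak (c), tidal wave (e), dicrotic notch (f)
# and dicrotic wave (g). Peaks and valleys come from sign changes of the
# first/second differences, gated by amplitude fractions of a (windowed)
# signal maximum: m for the main wave, (n, m) for the dicrotic wave, k for
# the notch, and a minimum upstroke slope a for the onset.

#' Threshold parameters for fiducial detection
#'
#' @param m Main-wave acceptance: fraction of the signal maximum a peak must
#'   exceed (default 0.7).
#' @param n Lower dicrotic-wave acceptance fraction; dicrotic peaks lie in
#'   `(n, m)` times the maximum (default 0.3).
#' @param k Notch acceptance: the dicrotic notch must stay above `k` times
#'   the maximum, separating it from the onset valley (default 0.2).
#' @param a Minimum first-difference (Pa/s) on the upstroke into the main
#'   wave; 0 disables the gate.
#' @param refractory Minimum spacing between successive main waves, in
#'   seconds (default 0.4).
#' @return A `threshold_params` list.
#' @export
threshold_params <- function(m = 0.7, n = 0.3, k = 0.2, a = 0, refractory = 0.4) {
  if (!(n > 0 && n < m && m <= 1)) {
    abort_pulsekit("Need 0 < n < m <= 1.", "pulsekit_bad_argument")
  }
  if (!(k > 0 && k < 1)) abort_pulsekit("Need 0 < k < 1.", "pulsekit_bad_argument")
  assert_scalar_number(a, "a", min = 0)
  assert_scalar_number(refractory, "refractory", min = 0, strict_min = TRUE)
  structure(list(m = m, n = n, k = k, a = a, refractory = refractory),
    class = "threshold_params")
}

#' First- and second-order differentials of a signal
#'
#' Central differences scaled to physical units (per second and per second
#' squared), with one-sided (first) / nearest-triple (second) stencils at
#' the edges so the outputs have the input's length.
#'
#' @param x Numeric signal (length >= 3).
#' @param fs Sampling rate in Hz.
#' @return A list with `first` and `second` numeric vectors.
#' @export
#' @examples
#' differentiate((0:10)^2, fs = 1)$second
differentiate <- function(x, fs = 1) {
  if (!is.numeric(x) || length(x) < 3) {
    abort_pulsekit("`x` must be numeric with length >= 3.", "pulsekit_bad_argument")
  }
  n <- length(x)
  first <- numeric(n)
  first[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2 * fs
  first[1] <- (x[2] - x[1]) * fs
  first[n] <- (x[n] - x[n - 1]) * fs
  second <- numeric(n)
  second[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) * fs^2
  second[1] <- second[2]
  second[n] <- second[n - 1]
  list(first = first, second = second)
}

# Greedy refractory pruning: among peaks closer than `min_gap` samples,
# keep the taller.
prune_refractory <- function(peaks, heights, min_gap) {
  if (length(peaks) < 2) return(peaks)
  keep <- order(heights, decreasing = TRUE)
  chosen <- integer(0)
  for (i in keep) {
    if (all(abs(peaks[i] - chosen) >= min_gap)) chosen <- c(chosen, peaks[i])
  }
  sort(chosen)
}

#' Detect pulse fiducial points by the differential-threshold method
#'
#' Locates, per beat: the main-wave peak c (local maximum above `m` times
#' the windowed signal maximum, refractory-filtered), the onset valley b
#' (minimum of the inter-main-wave interval, gated by upstroke slope `a`),
#' the dicrotic wave g (last local maximum between `n` and `m` times the
#' maximum after the main wave), the dicrotic notch f (minimum between c
#' and g, accepted when it stays above `k` times the maximum), and the
#' tidal wave e (local maximum between c and f, or the first descending-limb
#' inflection when the tidal wave is only a shoulder). All thresholds are
#' relative, so detections are invariant to amplitude scaling.
#'
#' @param x A pulse record data frame (baseline-subtracted) or numeric signal.
#' @param fs Sampling rate in Hz (required for numeric input).
#' @param params A [threshold_params()].
#' @param max_window_s Width (s) of the sliding window over which the
#'   reference maximum is taken; `Inf` uses the whole-signal maximum.
#' @return A `fiducial_points` tibble with one row per beat and 1-based
#'   sample indices `b`, `c`, `e`, `f`, `g` (`e`, `f`, `g` may be `NA`);
#'   attributes `fs`, `params`, and `counts` (per-point detections).
#' @export
#' @examples
#' rec <- synthesize_record(make_template("Pingmai"), 6, noise = zero_noise())
#' detect_fiducials(subtract_baseline(rec))
detect_fiducials <- function(x, fs = NULL, params = threshold_params(),
                             max_window_s = 10) {
  sig <- resolve_signal(x, fs)
  stopifnot(inherits(params, "threshold_params"))
  y <- sig$signal - min(sig$signal)
  nsamp <- length(y)
  fs <- sig$fs

  refmax <- if (is.finite(max_window_s) && max_window_s * fs < nsamp) {
    as.numeric(zoo::rollapply(zoo::zoo(y), width = round(max_window_s * fs),
      FUN = max, partial = TRUE, align = "center"))
  } else {
    rep(max(y), nsamp)
  }

  dd <- differentiate(y, fs)
  maxima <- local_maxima(y)
  minima <- local_minima(y)

  c_cand <- maxima[y[maxima] > params$m * refmax[maxima] & dd$second[maxima] < 0]
  c_idx <- prune_refractory(c_cand, y[c_cand], params$refractory * fs)
  if (length(c_idx) == 0) {
    abort_pulsekit("No main wave found; check the `m` threshold.",
      "pulsekit_no_main_wave")
  }

  beats <- purrr::map_dfr(seq_along(c_idx), function(i) {
    ci <- c_idx[i]
    lo <- if (i == 1) 1L else c_idx[i - 1] + 1L
    hi <- if (i == length(c_idx)) nsamp else c_idx[i + 1] - 1L
    if (ci - lo < 2) return(NULL)
    # onset: deepest point of the inter-main-wave interval, slope-gated
    pre <- lo:(ci - 1L)
    bi <- pre[which.min(y[pre])]
    if (max(dd$first[bi:ci]) <= params$a) return(NULL)

    gi <- NA_integer_
    fi <- NA_integer_
    ei <- NA_integer_
    post <- maxima[maxima > ci & maxima <= hi]
    g_cand <- post[y[post] > params$n * refmax[post] &
      y[post] < params$m * refmax[post]]
    if (length(g_cand) > 0) {
      gi <- g_cand[length(g_cand)]
      valley <- (ci + 1L):(gi - 1L)
      if (length(valley) > 0) {
        # the notch is the valley immediately preceding the dicrotic wave:
        # take the last local minimum before g (the deepest minimum can be
        # the dip between the main and tidal waves instead)
        vmin <- minima[minima > ci & minima < gi]
        fi <- if (length(vmin) > 0) vmin[length(vmin)] else
          valley[which.min(y[valley])]
        if (y[fi] <= params$k * refmax[fi]) {
          fi <- NA_integer_
          gi <- NA_integer_
        }
      } else {
        gi <- NA_integer_
      }
    }
    if (!is.na(fi)) ei <- find_tidal_point(y, ci, fi)
    tibble(beat = i, b = bi, c = ci, e = ei, f = fi, g = gi)
  })

  if (nrow(beats) > 0) beats$beat <- seq_len(nrow(beats))
  counts <- vapply(c("b", "c", "e", "f", "g"), function(p) sum(!is.na(beats[[p]])),
    integer(1))
  class(beats) <- c("fiducial_points", class(beats))
  attr(beats, "fs") <- fs
  attr(beats, "params") <- params
  attr(beats, "counts") <- counts
  beats
}

#' @export
print.fiducial_points <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf(
    "<fiducial_points> %d beats (b:%d c:%d e:%d f:%d g:%d)\n",
    nrow(x), cnt[["b"]], cnt[["c"]], cnt[["e"]], cnt[["f"]], cnt[["g"]]
  ))
  NextMethod()
}
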