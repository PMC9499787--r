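# Synthetic pulse record generation: beat train + initial-pressure baseline
# + slow drift + high-frequency interference + white noise, on nominally
# uniform timestamps with optional jitter, together with ground-truth
# fiducial indices for every complete beat.

#' Noise specification for synthetic pulse records
#'
#' All amplitudes are in Pa, frequencies in Hz, jitter in seconds. The
#' defaults emulate the interference a wrist pressure sensor picks up: slow
#' respiratory/motion baseline wander (below 0.5 Hz), narrow-band
#' high-frequency interference (above 20 Hz), broadband thermal noise, and
#' slight non-uniformity of the hardware sampling clock.
#'
#' @param drift_amplitude Baseline-drift amplitude (Pa).
#' @param drift_frequency Drift frequency; must be < 0.5 Hz.
#' @param hf_amplitude High-frequency interference amplitude (Pa).
#' @param hf_frequency Interference frequency; must be > 20 Hz.
#' @param white_sd Standard deviation of additive white noise (Pa).
#' @param timestamp_jitter_sd Standard deviation of timestamp jitter (s).
#' @return A `noise_spec` list.
#' @export
#' @examples
#' noise_spec()
#' noise_spec(drift_amplitude = 0, hf_amplitude = 0, white_sd = 0,
#'   timestamp_jitter_sd = 0) # noiseless
noise_spec <- function(drift_amplitude = 60, drift_frequency = 0.25,
                       hf_amplitude = 15, hf_frequency = 35,
                       white_sd = 5, timestamp_jitter_sd = 5e-4) {
  assert_scalar_number(drift_amplitude, "drift_amplitude", min = 0)
  assert_scalar_number(hf_amplitude, "hf_amplitude", min = 0)
  assert_scalar_number(white_sd, "white_sd", min = 0)
  assert_scalar_number(timestamp_jitter_sd, "timestamp_jitter_sd", min = 0)
  if (drift_frequency >= 0.5) {
    abort_pulsekit("`drift_frequency` must be below 0.5 Hz.", "pulsekit_bad_argument")
  }
  if (hf_frequency <= 20) {
    abort_pulsekit("`hf_frequency` must be above 20 Hz.", "pulsekit_bad_argument")
  }
  structure(
    list(
      drift_amplitude = drift_amplitude, drift_frequency = drift_frequency,
      hf_amplitude = hf_amplitude, hf_frequency = hf_frequency,
      white_sd = white_sd, timestamp_jitter_sd = timestamp_jitter_sd
    ),
    class = "noise_spec"
  )
}

#' @rdname noise_spec
#' @export
zero_noise <- function() {
  noise_spec(
    drift_amplitude = 0, hf_amplitude = 0, white_sd = 0,
    timestamp_jitter_sd = 0
  )
}

new_pulse_record <- function(time, pressure, label = NULL, fs_nominal = NULL,
                             source_id = "record", ground_truth = NULL) {
  out <- tibble(time = time, pressure = pressure)
  class(out) <- c("pulse_record", class(out))
  attr(out, "label") <- label
  attr(out, "fs") <- fs_nominal
  attr(out, "source_id") <- source_id
  attr(out, "ground_truth") <- ground_truth
  out
}

#' @export
print.pulse_record <- function(x, ...) {
  lab <- attr(x, "label") %||% "<unlabelled>"
  fs <- attr(x, "fs")
  cat(sprintf(
    "<pulse_record> %s, %s, %d samples%s\n",
    attr(x, "source_id") %||% "record", lab, nrow(x),
    if (is.null(fs)) "" else sprintf(" @ %g Hz nominal", fs)
  ))
  NextMethod()
}

#' Ground-truth fiducials of a pulse record
#'
#' @param record A synthetic `pulse_record`.
#' @return A tibble with one row per complete beat: `beat`, `onset_time`,
#'   and 1-based sample indices `b`, `c`, `e`, `f`, `g`, or `NULL` for
#'   records without ground truth.
#' @export
ground_truth <- function(record) {
  attr(record, "ground_truth")
}

#' Synthesize a pulse record from a template
#'
#' Generates `pressure = baseline_pressure + beat train + drift + HF noise +
#' white noise` sampled on nominally uniform timestamps with optional jitter
#' (the sampling clock of real acquisition hardware is not perfectly
#' uniform). Ground-truth fiducial indices (b, c, e, f, g) are extracted
#' from the noiseless waveform geometry for every complete beat: b and f as
#' the onset and dicrotic valleys, c and g as the main- and dicrotic-wave
#' peaks, and e as the tidal-wave peak or, when the tidal wave is only a
#' shoulder, the descending-limb inflection.
#'
#' @param template A `pulse_template` from [make_template()].
#' @param duration Record length in seconds (>= 2 beat periods).
#' @param fs Nominal sampling rate in Hz (>= 50).
#' @param noise A [noise_spec()]; default has mild drift, HF and white noise.
#' @param seed Integer seed; fixed seeds give bitwise-identical records.
#' @return A `pulse_record` tibble (`time`, `pressure`) with attributes
#'   `label`, `fs`, `source_id` and `ground_truth` (see [ground_truth()]).
#' @export
#' @examples
#' rec <- synthesize_record(make_template("Pingmai"), duration = 4, fs = 200,
#'   noise = zero_noise(), seed = 1)
#' ground_truth(rec)
synthesize_record <- function(template, duration, fs = 200,
                              noise = noise_spec(), seed = 0L) {
  stopifnot(inherits(template, "pulse_template"))
  assert_scalar_number(fs, "fs", min = 50)
  Tb <- template$beat_period
  if (duration < Tb) {
    abort_pulsekit("`duration` is too short for one complete beat.",
      "pulsekit_duration_too_short")
  }
  if (duration < 2 * Tb) {
    abort_pulsekit("`duration` must cover at least two beat periods.",
      "pulsekit_duration_too_short")
  }
  if (!inherits(noise, "noise_spec")) {
    abort_pulsekit("`noise` must be a noise_spec().", "pulsekit_bad_argument")
  }

  n <- floor(duration * fs)
  t_nom <- (seq_len(n) - 1) / fs
  draws <- with_seed(derive_seed(seed, template$class_label, 23L), {
    list(
      jitter = rnorm(n, 0, noise$timestamp_jitter_sd),
      white = rnorm(n, 0, noise$white_sd),
      phases = runif(2, 0, 2 * pi)
    )
  })
  # truncate jitter so timestamps stay strictly increasing
  jitter <- pmin(pmax(draws$jitter, -0.4 / fs), 0.4 / fs)
  time <- t_nom + jitter
  time[1] <- max(time[1], 0)

  onsets <- seq(0, duration - Tb, by = Tb)
  clean <- eval_beat_train(template, time, onsets)
  pressure <- template$baseline_pressure + clean +
    noise$drift_amplitude * sin(2 * pi * noise$drift_frequency * time + draws$phases[1]) +
    noise$hf_amplitude * sin(2 * pi * noise$hf_frequency * time + draws$phases[2]) +
    draws$white

  gt <- extract_ground_truth(template, time, clean, onsets)
  new_pulse_record(
    time, pressure,
    label = template$class_label, fs_nominal = fs,
    source_id = sprintf("synth-%s-%d", template$class_label, seed),
    ground_truth = gt
  )
}

# Fiducials of the noiseless sampled beat train, one row per complete beat.
extract_ground_truth <- function(template, time, clean, onsets) {
  Tb <- template$beat_period
  comp <- template$components
  tf <- comp$time_frac[match(c("c", "e", "g"), comp$wave)]
  t_end <- time[length(time)]
  window <- function(t0, t1) which(time >= t0 & time <= t1)

  rows <- purrr::map_dfr(seq_along(onsets), function(k) {
    o <- onsets[k]
    if (o + Tb > t_end + 1e-9) return(NULL)
    wc <- window(o, o + (tf[1] + tf[2]) / 2 * Tb)
    ci <- wc[which.max(clean[wc])]
    wg <- window(o + (tf[2] + tf[3]) / 2 * Tb, min(o + Tb, t_end))
    # the dicrotic peak is a local maximum inside the window; the raw
    # argmax can sit on the window edge (tidal-wave tail) instead
    lmg <- wg[wg %in% (wg[1] + local_maxima(clean[wg]) - 1L)]
    gi <- if (length(lmg) > 0) lmg[which.max(clean[lmg])] else
      wg[which.max(clean[wg])]
    wf <- window(o + tf[2] * Tb, time[gi])
    fi <- wf[which.max(-clean[wf])]
    wb <- window(max(0, o - 0.25 * Tb), time[ci])
    bi <- wb[which.max(-clean[wb])]
    ei <- find_tidal_point(clean, ci, fi)
    tibble(
      beat = k, onset_time = time[bi],
      b = bi, c = ci, e = ei, f = fi, g = gi
    )
  })
  rows
}

# Tidal point between main-wave peak ci and notch fi: a distinct local
# maximum when one exists, otherwise the first inflection (second difference
# crossing from negative to positive) on the descending limb; NA when the
# limb has no such structure.
find_tidal_point <- function(x, ci, fi) {
  if (fi - ci < 4) return(NA_integer_)
  seg <- x[ci:fi]
  lm <- local_maxima(seg)
  lm <- lm[lm > 1 & lm < length(seg)]
  if (length(lm) > 0) return(ci + lm[1] - 1L)
  d2 <- diff(seg, differences = 2)
  cross <- which(d2[-length(d2)] < 0 & d2[-1] >= 0)
  if (length(cross) == 0) return(NA_integer_)
  ci + cross[1] + 1L
}

#' Generate a labeled collection of synthetic pulse records
#'
#' @param counts Named integer vector or list mapping Mai class names to the
#'   number of records to generate (all >= 1).
#' @param duration,fs,noise Passed to [synthesize_record()].
#' @param seed Base seed; each record uses a seed derived deterministically
#'   from `(seed, class, index)`.
#' @return A tibble with columns `source_id`, `label`, `record` (list column
#'   of `pulse_record`s).
#' @export
#' @examples
#' ds <- make_dataset(c(Pingmai = 2, Jimai = 1), duration = 4,
#'   noise = zero_noise(), seed = 1)
#' ds$label
make_dataset <- function(counts, duration = 12, fs = 200,
                         noise = noise_spec(), seed = 0L) {
  counts <- unlist(counts)
  if (length(counts) == 0) {
    abort_pulsekit("`counts` must name at least one class.", "pulsekit_bad_argument")
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    abort_pulsekit("`counts` must be named by class.", "pulsekit_bad_argument")
  }
  purrr::walk(names(counts), assert_mai_class)
  if (any(counts < 1)) {
    abort_pulsekit("All class counts must be >= 1.", "pulsekit_bad_argument")
  }

  purrr::map_dfr(names(counts), function(cls) {
    purrr::map_dfr(seq_len(counts[[cls]]), function(i) {
      rec_seed <- derive_seed(seed, cls, i)
      template <- make_template(cls, seed = rec_seed)
      rec <- synthesize_record(template, duration, fs, noise, seed = rec_seed)
      attr(rec, "source_id") <- sprintf("synth-%s-%03d", cls, i)
      tibble(
        source_id = attr(rec, "source_id"), label = cls, record = list(rec)
      )
    })
  })
}
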