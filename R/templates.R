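# Class templates for the synthetic pulse generator. Each beat is modelled
# as three Gaussian lobes — main wave (c), tidal wave (e), dicrotic wave (g)
# — riding on a broad systolic-base hump plus a smooth decaying intra-beat
# baseline (together these keep the dicrotic notch in the physiological
# 0.25-0.40 range of pulse height); the notch (f) is the local minimum
# between the e and g lobes, and the onset (b) is the inter-beat valley.
# The ten default templates caricature the named Mai types (period,
# relative lobe amplitudes, timing); they aim at mutual separability, not
# hemodynamic fidelity.

# period [s], main amplitude [Pa], relative amplitude and timing (fraction of
# the period) of the three lobes, lobe widths as period fractions.
mai_template_table <- function() {
  tibble::tribble(
    ~class_label, ~period, ~amp, ~e_amp, ~g_amp, ~c_frac, ~e_frac, ~g_frac, ~c_w, ~e_w, ~g_w,
    "Changmai", 0.95, 650, 0.50, 0.40, 0.16, 0.40, 0.65, 0.075, 0.075, 0.080,
    "Chimai",   1.20, 550, 0.40, 0.42, 0.14, 0.35, 0.58, 0.055, 0.062, 0.075,
    "Dongmai",  0.60, 700, 0.38, 0.40, 0.15, 0.33, 0.56, 0.035, 0.058, 0.068,
    "Huamai",   0.75, 620, 0.38, 0.55, 0.15, 0.33, 0.60, 0.045, 0.058, 0.072,
    "Huanmai",  1.00, 500, 0.48, 0.38, 0.15, 0.36, 0.60, 0.060, 0.065, 0.075,
    "Jimai",    0.48, 680, 0.40, 0.40, 0.15, 0.34, 0.56, 0.040, 0.055, 0.065,
    "Pingmai",  0.80, 600, 0.45, 0.42, 0.15, 0.35, 0.60, 0.066, 0.078, 0.092,
    "Shimai",   0.85, 900, 0.50, 0.44, 0.16, 0.37, 0.62, 0.055, 0.065, 0.075,
    "Weimai",   0.88, 250, 0.34, 0.37, 0.15, 0.34, 0.57, 0.050, 0.058, 0.068,
    "Xuanmai",  0.78, 640, 0.46, 0.40, 0.14, 0.30, 0.55, 0.055, 0.068, 0.075
  )
}

#' Build a synthetic pulse template for a Mai class
#'
#' Returns the beat-shape parameters for one of the ten Mai classes: beat
#' period, the centres/amplitudes/widths of the main-wave (c), tidal-wave (e)
#' and dicrotic-wave (g) Gaussian lobes, a smooth decaying intra-beat
#' baseline, and the resting baseline pressure. A nonzero `seed` adds small
#' deterministic within-class variation (a few percent on period, amplitudes
#' and timing) so repeated records of one class are not identical.
#'
#' @param class_label One of [mai_classes()].
#' @param seed Integer seed for within-class variation; the same
#'   `(class_label, seed)` pair always yields the identical template.
#' @return A `pulse_template` object.
#' @export
#' @examples
#' make_template("Pingmai", 0)
make_template <- function(class_label, seed = 0L) {
  assert_mai_class(class_label)
  row <- mai_template_table()[mai_template_table()$class_label == class_label, ]

  jit <- with_seed(derive_seed(seed, class_label, 11L), {
    list(
      period = exp(rnorm(1, 0, 0.03)),
      amp = exp(rnorm(1, 0, 0.06)),
      rel = exp(rnorm(2, 0, 0.05)),
      frac = rnorm(3, 0, 0.006),
      width = exp(rnorm(3, 0, 0.05))
    )
  })

  period <- row$period * jit$period
  amp <- row$amp * jit$amp
  # keep the secondary lobes inside the detectability corridor relative to c
  e_amp <- min(max(row$e_amp * jit$rel[1], 0.30), 0.56)
  g_amp <- min(max(row$g_amp * jit$rel[2], 0.34), 0.58)
  fracs <- pmin(pmax(c(row$c_frac, row$e_frac, row$g_frac) + jit$frac, 0.08), 0.70)
  fracs <- sort(fracs)
  widths <- c(row$c_w, row$e_w, row$g_w) * jit$width

  components <- tibble(
    wave = c("c", "e", "g"),
    time_frac = fracs,
    amplitude = amp * c(1, e_amp, g_amp),
    width = widths * period
  )

  out <- structure(
    list(
      class_label = class_label,
      beat_period = period,
      components = components,
      baseline_pressure = 2000,
      base_amp = 0.25 * amp,
      base_frac = 0.34,
      base_width = 0.17 * period,
      decay_amp = 0.12 * amp,
      decay_rise = 0.04 * period,
      decay_tau = 0.20 * period,
      seed = as.integer(seed)
    ),
    class = "pulse_template"
  )
  validate_template(out)
  out
}

validate_template <- function(template) {
  comp <- template$components
  amps <- comp$amplitude[match(c("c", "e", "g"), comp$wave)]
  if (!(amps[1] > amps[2] && amps[1] > amps[3])) {
    abort_pulsekit("Main-wave amplitude must exceed tidal and dicrotic amplitudes.",
      "pulsekit_bad_template")
  }
  if (is.unsorted(comp$time_frac, strictly = TRUE)) {
    abort_pulsekit("Component centres must be ordered c < e < g within the beat.",
      "pulsekit_bad_template")
  }
  invisible(template)
}

#' @export
print.pulse_template <- function(x, ...) {
  cat(sprintf(
    "<pulse_template> %s: period %.3f s, main amplitude %.0f Pa\n",
    x$class_label, x$beat_period, max(x$components$amplitude)
  ))
  print(x$components)
  invisible(x)
}

# Evaluate the noiseless beat train (without baseline pressure) at times `t`
# for beats with onsets `onsets`.
eval_beat_train <- function(template, t, onsets) {
  p <- numeric(length(t))
  comp <- template$components
  Tb <- template$beat_period
  for (o in onsets) {
    tau <- t - o
    live <- tau > -0.75 * Tb & tau < 1.75 * Tb
    if (!any(live)) next
    tl <- tau[live]
    contrib <- numeric(length(tl))
    for (i in seq_len(nrow(comp))) {
      contrib <- contrib +
        comp$amplitude[i] * exp(-(tl - comp$time_frac[i] * Tb)^2 / (2 * comp$width[i]^2))
    }
    contrib <- contrib + template$base_amp *
      exp(-(tl - template$base_frac * Tb)^2 / (2 * template$base_width^2))
    pos <- tl > 0
    contrib[pos] <- contrib[pos] + template$decay_amp *
      (1 - exp(-(tl[pos] / template$decay_rise)^2)) * exp(-tl[pos] / template$decay_tau)
    p[live] <- p[live] + contrib
  }
  p
}

# Noiseless single-beat waveform on a fine grid, used for template
# separability checks and documentation plots.
template_beat <- function(template, n = 512) {
  tau <- seq(0, template$beat_period, length.out = n)
  tibble(tau = tau, pressure = eval_beat_train(template, tau, 0))
}
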