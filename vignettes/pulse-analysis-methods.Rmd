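---
title: "Pulse waveform analysis with pulsekit: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse waveform analysis with pulsekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsekit)
```

## The problem

Arterial pressure pulse recordings carry diagnostic information in their
beat-to-beat morphology: the systolic main wave, the tidal wave on the
descending limb, the dicrotic notch, and the dicrotic rebound wave. Two
kinds of interference dominate raw sensor data: slow baseline wander
(below 0.5 Hz, from respiration and hand motion) and high-frequency noise
(above 20 Hz, from electronics and the environment), while essentially all
pulse energy lies below 20 Hz. pulsekit implements a complete analysis
chain for such recordings: denoising (two alternative methods), fiducial
point detection, wavelet-energy features, onset-anchored segmentation, and
a fixed-architecture 1-D convolutional classifier for ten traditional
pulse (Mai) categories. Because clinical pulse databases are rarely
shareable, the package also ships a synthetic generator that produces
labeled records with known ground-truth fiducials, so every stage is
testable end to end.

## Wavelet band-zeroing denoiser

The denoiser decomposes a signal of length $L$ into $N = \lfloor \log_2 L
\rfloor$ dyadic levels with the Daubechies-7 wavelet. Detail level $j$
nominally covers $(f_s/2^{j+1},\, f_s/2^{j}]$ Hz. Three groups of
coefficients are zeroed before reconstruction:

* every detail level whose band lies entirely above the 20 Hz
  high-frequency cutoff (levels 1–2 at $f_s = 200$ Hz);
* the levels between the single-cycle level $N_1 = \lceil \log_2(L/M)
  \rceil$ (with $M$ the number of beats, estimated from the dominant
  0.5–4 Hz spectral peak) and $N$, inclusive — these carry the inter-beat
  baseline of a quasi-periodic signal;
* the final approximation.

For the canonical case $L = 1000$, $f_s = 200$, $M = 7$ this zeroes
exactly cD1, cD2, cD8, cD9, cA9.

**Boundary handling.** Two modes are provided, and the defaults differ by
purpose:

* `"periodic"` (default for `wavelet_decompose()` and the energy
  features): the signal is wrapped, odd lengths padded by repeating the
  last sample. On a fully even cascade (e.g. $L = 1024$) this transform is
  orthogonal — coefficient energies sum exactly to the signal energy and
  band-zeroing is an idempotent orthogonal projection. On other lengths
  each odd level adds one padding coefficient, leaving a residual
  re-zeroing energy of order $10^{-7}$ of the total at $L = 1000$.
* `"symmetric"` (default for `denoise_wavelet()`): half-sample reflection.
  Records are not periodic — drift leaves the two ends at different
  levels — and circular wrapping would ring at the record edges, so the
  denoiser prefers reflection. The price is boundary-redundant
  coefficients: re-analysing a reconstruction does not reproduce the
  zeroed coefficients exactly (a second pass removes roughly 2–3% in
  relative L2), which is intrinsic to symmetric extension, not an
  implementation artifact.

Both modes are verified coefficient-for-coefficient against an independent
reference implementation in the test suite. Dyadic band edges are kept
exact internally ($3.125$ Hz, not the display rounding $3.1$).

A consequence worth knowing: dyadic bands are not brick-wall filters. A
pure tone close to a band edge (30 Hz, near the 25 Hz cD2/cD3 edge at
$f_s=200$) keeps roughly a third of its amplitude after zeroing cD1–cD2,
while a tone at the band centre (40 Hz) is attenuated to below 1%.

## EEMD / Hilbert denoiser

The alternative denoiser decomposes the signal by ensemble empirical mode
decomposition: EMD is run on `ensemble_size` (default $M = 100$)
white-noise-perturbed copies (noise s.d. $0.2\,\sigma_x$ by default) and
the intrinsic mode functions (IMFs) are averaged index-wise. Sifting uses
natural cubic-spline envelopes through the extrema with the first/last two
extrema mirrored across the ends, the standard normalized
squared-difference stop criterion at 0.2, and a cap of 10 sifts per IMF.

Each IMF is summarized by one number: the amplitude-weighted mean of its
instantaneous frequency (from the FFT-based analytic signal, phase
unwrapped, central differences), trimming 5% of samples at each edge
against Hilbert edge effects. A per-sample frequency rule would discard no
IMF cleanly; the weighted mean makes the keep/drop decision well defined.
IMFs with mean frequency outside $[0.5, 20]$ Hz are dropped, and the
residue (monotone trend) is always dropped as baseline. The denoised
signal is the sum of the kept IMFs.

## Fiducial detection by differential thresholds

Detection works on the baseline-subtracted signal using its first and
second central differences and amplitude gates relative to a reference
maximum (by default the maximum over a sliding 10 s window, so slow gain
changes do not silence later beats; the whole-signal maximum is available
via `max_window_s = Inf`):

* **c (main wave)** — local maxima above `m` (default 0.7) times the
  reference maximum, with negative curvature, then refractory-filtered
  (default 0.4 s, keeping the taller of too-close peaks).
* **b (onset)** — the deepest point of each inter-main-wave interval,
  gated by the upstroke slope parameter `a` (default 0, disabled). The
  onset valley is always below the `k`-gated notch, so the interval
  minimum is the onset; this formulation is robust on the near-flat
  diastolic tail where "the last local minimum" is numerically fragile.
* **g (dicrotic wave)** — the last local maximum between `n` (default
  0.3) and `m` times the reference maximum after the main wave.
* **f (dicrotic notch)** — the last local minimum before g (the deepest
  minimum between c and g can be the dip between the main and tidal waves
  instead). The notch must stay above `k` (default 0.2) times the
  reference maximum; a deeper valley is an onset, and the beat's f and g
  slots are reported as missing.
* **e (tidal wave)** — a distinct local maximum between c and f when one
  exists, otherwise the first inflection (second difference crossing from
  negative to positive) on the descending limb.

All gates are relative, so detections are invariant to amplitude scaling.
`m`, `n`, `k`, `a` and the refractory period carry no published reference
values; the defaults were chosen on the synthetic templates and are
CLI-tunable. Plateaus resolve to their first index.

## Wavelet-energy features

`wavelet_energy()` performs a 5-level periodized decomposition and reports
the sum of squared coefficients of (cA5, cD5, cD4, cD3, cD2, cD1) plus the
shares normalized by total energy. At $f_s = 200$ the six subbands span
0–3.125, 3.125–6.25, 6.25–12.5, 12.5–25, 25–50 and 50–100 Hz. Energies are
computed on the decimated coefficients as-is (no per-level rescaling);
with the periodized (orthogonal) transform the shares are an exact energy
partition. A clean normal pulse concentrates over 99% of its energy below
6.25 Hz; after wavelet preprocessing in the same basis the cD1/cD2 shares
are numerically zero (and about $10^{-4}$ when the symmetric-boundary
denoiser is used instead, the mismatch living at the record edges).

## Segmentation and augmentation

Raw timestamps are not perfectly uniform, so each record is interpolated
by a natural cubic spline (the continuous-time densification of the
record; evaluating the spline directly at the output instants is exactly
equivalent to a dense grid followed by interception, for any densification
factor) and resampled at exactly 50 Hz. Fiducial detection then runs on
the 50 Hz series, and one 300-sample (6 s) segment is cut at every onset
that leaves a full window — successive onsets give overlapping windows,
which is the cross-interception augmentation. Each segment is min–max
scaled to $[0, 1]$ (switchable); the classifier should see shape, not
sensor gain.

The train/test split is a single unstratified random partition at 7:3 with
floor-to-train rounding, so 677 segments give exactly (473, 204). Class
proportions are left to chance deliberately — stratification is not used.
Overlapping segments of one record may land on both sides of the split;
`group_by_record = TRUE` offers the stricter protocol, but the default
matches the augment-then-split-randomly design this pipeline reproduces,
which is also why its test metrics must be read as optimistic for that
protocol, not as generalization estimates.

## The classifier

The network is fixed: two 100-filter width-10 valid convolutions, width-3
stride-3 max pooling, two 160-filter width-10 convolutions, global average
pooling, dropout 0.5, and a 10-way softmax head, trained with categorical
cross-entropy. The layer trace on a 300-sample input is
300×1 → 291×100 → 282×100 → 94×100 → 85×160 → 76×160 → 1×160 → 1×160 → 10,
and `shape_trace()` computes it by pure arithmetic. Choices the
architecture specification leaves open are set as follows and are
configurable: rectified-linear hidden activations, Adam with learning rate
$10^{-3}$, batch size 32, 50 epochs, no early stopping, He initialization,
inverted dropout (survivors scaled by 2 in training, inference untouched).

Training runs in single precision with BLAS matrix kernels; minibatch
order and dropout draws are generated from the seed on the R side, so a
run is bit-reproducible for a fixed seed. A double-precision forward and
backward pass implemented independently in R serves as the reference in
the test suite, where backpropagation is checked against central finite
differences on a shrunken clone of the architecture.

Evaluation reports per-class precision, recall and F1, their macro
averages over classes present in the test set (absent classes give NA,
not 0), overall accuracy, and a confusion matrix oriented rows =
predicted, columns = true.

## The synthetic generator

Each beat is a sum of three Gaussian lobes — main wave, tidal wave,
dicrotic wave — on a broad systolic-base hump plus a smoothly rising,
exponentially decaying intra-beat baseline; these two base terms keep the
dicrotic notch in the physiological 0.25–0.4 range of pulse height. The
ten class templates caricature the named Mai types through period (0.48 s
for the rapid Jimai to 1.2 s for the slow Chimai), relative lobe
amplitudes (prominent dicrotic wave for Huamai, high early tidal wave for
Xuanmai, 250 Pa total amplitude for the faint Weimai versus 900 Pa for the
replete Shimai) and timing. Records add the 2000 Pa sensor baseline,
sinusoidal drift (default 60 Pa at 0.25 Hz), narrow-band high-frequency
interference (15 Pa at 35 Hz), white noise (5 Pa), and truncated Gaussian
timestamp jitter (0.5 ms), emulating a non-uniform hardware clock.

Ground-truth fiducials are extracted from the noiseless sampled waveform
geometry within template-anchored windows, so "truth" is a property of the
generated curve, not of the nominal lobe parameters; the onset is the true
inter-beat minimum to within one sample by construction.

What the generator does **not** emulate: beat-to-beat period variability
within a record, amplitude fatigue, sensor saturation, motion artifacts,
or genuine physiological morphology. Templates of different classes are
separable by design — the documented pairwise margin is 8% normalized L2
on a common grid, with the closest pairs further apart in period and
amplitude. Passing the end-to-end training criteria on these data
therefore demonstrates that the pipeline is wired correctly and that the
classifier can learn the ten-class morphology; it says
nothing about accuracy on clinical recordings.

Two template families are intentionally spiky (Dongmai, Jimai) and carry
harmonics above 6.25 Hz; the >99% low-band energy property is asserted
for the smooth (healthy-morphology) classes.

## Problem sizes and determinism

The shipped tests and the acceptance script use the full 677-segment
ten-class dataset (12 s records at 200 Hz, resampled to 50 Hz) and train
for the configured 50 epochs; EEMD tests use ensembles of 10–50 members on
800–2000-sample signals. Every stochastic step — template jitter, noise,
EEMD ensembles, the split, network initialization, minibatch order,
dropout — derives from one user seed through a deterministic sub-seed
stream, and repeated runs are bitwise identical.

## Known limitations

* Only the db7 wavelet is shipped; the level-selection arithmetic is
  wavelet-independent but the filter bank is not pluggable.
* The differential-threshold detector expects denoised input; on raw noisy
  signals spurious local extrema degrade e/f/g before b/c.
* The beat counter assumes a dominant fundamental in 0.5–4 Hz; heavily
  non-stationary rhythms would need fiducial-based counting.
* EEMD completeness holds only up to the residual ensemble noise
  ($\propto \mathrm{noise\_sd}/\sqrt{M}$); exact completeness is EMD's.
* The CNN trainer is CPU-bound single precision; it is built for this
  fixed architecture, not as a general deep-learning engine.
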