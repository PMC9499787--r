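# Shared fixtures: clean (noise-free) records are the reference inputs for
# detector and denoiser checks; built once per test run.

clean_record <- function(class = "Pingmai", seed = 1, duration = 12, fs = 200) {
  synthesize_record(make_template(class, seed), duration, fs,
    noise = zero_noise(), seed = seed)
}

rel_l2_err <- function(a, b) sqrt(sum((a - b)^2)) / sqrt(sum(b^2))

# drift-only contamination: clean beats plus 0.1 Hz baseline wander
drift_record <- function(seed = 1, duration = 12, fs = 200) {
  synthesize_record(make_template("Pingmai", seed), duration, fs,
    noise = noise_spec(
      drift_amplitude = 150, drift_frequency = 0.1,
      hf_amplitude = 0, white_sd = 0, timestamp_jitter_sd = 0
    ),
    seed = seed)
}
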