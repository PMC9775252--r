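# Shared fixtures: small deterministic signals and reduced-size
# configurations. Everything is generated in code; no data files.

fs_test <- 500

# Pure sinusoid recording: one row per frequency.
sine_recording <- function(freqs, duration = 20, fs = fs_test,
                           labels = paste0("ch", seq_along(freqs))) {
  t <- seq_len(duration * fs) / fs
  eeg_recording(t(sapply(freqs, function(f) sin(2 * pi * f * t))), fs, labels)
}

# Interior sample indices (masks filter edge transients).
interior <- function(n, fs = fs_test, edge_s = 2) (edge_s * fs):(n - edge_s * fs)

rms <- function(x) sqrt(mean(x^2))

# Single-band simulation config with uniform all-channel coupling; the
# workhorse of the estimator-closure tests.
closure_config <- function(kappa, n_channels = 6, duration = 60,
                           band_name = "beta", jitter = 0, noise_sd = 0,
                           seed = 1) {
  labels <- retained_channels()[seq_len(n_channels)]
  key <- paste("MDD", "pre", band_name, sep = ".")
  coupling <- stats::setNames(
    list(list(coupling_spec(kappa, phase_jitter_sd = jitter))), key)
  simulation_config(
    n_per_group = 1, sampling_rate = fs_test,
    segment_layout = c(pre = duration),
    channel_labels = labels,
    bands = canonical_bands(band_name),
    band_coupling = coupling,
    band_amplitudes = stats::setNames(1, band_name),
    noise_sd = noise_sd, seed = seed)
}

# Recovered PLV matrix for one closure replicate: generate, band-isolate,
# Hilbert phase, PLV -- the estimator side of the generator/estimator loop.
closure_plv <- function(config, band_name = "beta", subject_seed = 1) {
  lr <- generate_coupled_recording(config, "MDD", "pre", subject_seed)
  band <- decompose_bands(lr$recording, canonical_bands(band_name))[[band_name]]
  plv_matrix(instantaneous_phase(band, 1))$values
}

offdiag <- function(m) m[upper.tri(m)]

# Reduced-size cohort config for pipeline tests: full channel count,
# short segments (still >= 3 x the longest filter).
tiny_cohort_config <- function(n_per_group = 2, seed = 7,
                               layout = c(pre = 12, post = 12),
                               n_channels = 19) {
  labels <- retained_channels()[seq_len(n_channels)]
  coupling <- default_band_coupling()
  if (n_channels < 19) {
    # restrict community memberships to the retained subset
    coupling <- lapply(coupling, function(specs) {
      lapply(specs, function(sp) {
        sp$channels <- intersect(sp$channels, labels)
        sp
      })
    })
  }
  simulation_config(n_per_group = n_per_group,
                    segment_layout = layout,
                    channel_labels = labels,
                    band_coupling = coupling,
                    seed = seed)
}

tiny_pipeline_config <- function(seed = 7, n_per_group = 2) {
  pipeline_config(synth = list(n_per_group = n_per_group,
                               segment_layout = c(pre = 12, post = 12)),
                  n_permutations = 99, k_folds = 4, seed = seed)
}
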