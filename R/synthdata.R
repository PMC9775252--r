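# Synthetic EEG cohort generator with controlled band-specific phase
# coupling.
#
# Generative model, per band: one latent "driver" phase theta(t) wanders
# inside the band. Each coupled channel mixes the driver phasor with an
# independent narrowband phasor:
#
#     z_c(t) = kappa * exp(i theta(t)) + (1 - kappa) * exp(i zeta_c(t))
#
# and contributes a_band * Re(z_c) to the channel signal. kappa = 1 locks
# channel phases together (PLV = 1); kappa = 0 makes them independent
# wandering phases (PLV at the finite-sample null level); the expected PLV
# of a coupled pair is a smooth strictly increasing function of kappa.
# Group and condition differences are encoded purely in the kappa values
# attached to channel communities.
#
# Each channel sees the driver through a fixed random phase offset
# delta_c (constant per subject x band x channel, shared across
# conditions). PLV is invariant to constant offsets, but the offsets keep
# the driver out of the common-mode average, mimicking the varied source
# topographies of real scalp EEG -- without them the common average
# reference would subtract the driver itself and destroy the coupling it
# is supposed to carry.

#' Specify phase coupling for a channel community
#'
#' All listed channels share one latent band driver, mixed in at weight
#' `strength`. Different communities of the same band use different
#' strengths but the same driver, so between-community pairs couple at the
#' geometric mean of the two resultants.
#'
#' @param strength Coupling weight kappa in `[0, 1]`: 0 = independent
#'   phases, 1 = identical phases.
#' @param channels Character vector of member channels, or `NULL` for all
#'   channels of the configuration.
#' @param phase_jitter_sd Standard deviation, in radians, of the smooth
#'   phase jitter added to each channel (default 0.15).
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(strength, channels = NULL, phase_jitter_sd = 0.15) {
  if (!is_number(strength) || strength < 0 || strength > 1)
    plv_stop("config", "coupling strength must lie in [0, 1]")
  if (!is_number(phase_jitter_sd) || phase_jitter_sd < 0)
    plv_stop("config", "phase_jitter_sd must be >= 0")
  structure(list(strength = strength, channels = channels,
                 phase_jitter_sd = phase_jitter_sd),
            class = "coupling_spec")
}

# Channel communities used by the default effect configuration.
.frontal <- c("Fp1", "Fp2", "Fpz", "F3", "F4", "F7", "F8")
.central <- c("Cz", "C3", "C4", "T7", "T8")
.posterior <- c("Pz", "P3", "P4", "P7", "P8", "O1", "O2")

#' Default band-coupling map encoding the study's effect directions
#'
#' Each band has a "core" community coupled at a fixed high strength
#' (0.85) and a "secondary" community whose strength varies with group and
#' condition, so that binarization at 80% of the maximum includes or
#' excludes the secondary community depending on the state:
#'
#' * delta: MDD coupling exceeds HC and decreases after stimulation;
#' * beta: MDD coupling is below HC and increases after stimulation;
#' * alpha: MDD coupling is below HC and increases after stimulation;
#' * theta: HC slightly above MDD, slight increase after stimulation.
#'
#' Only the directions of these effects are meaningful; the magnitudes are
#' package conventions chosen to put secondary-community PLVs clearly on
#' one or the other side of the binarization cut.
#'
#' @param effect `"strong"` (default) for the direction-encoding preset,
#'   or `"none"` for a null configuration in which every cell couples
#'   identically (useful for calibration tests).
#' @return Named list (`"group.condition.band"` -> list of
#'   [coupling_spec()]s) covering all 2 groups x 3 conditions x 4 bands.
#' @export
default_band_coupling <- function(effect = c("strong", "none")) {
  effect <- match.arg(effect)
  core <- list(delta = .frontal, theta = .central, alpha = .posterior,
               beta = .central)
  sec <- list(delta = .posterior, theta = .posterior, alpha = .frontal,
              beta = .frontal)
  # secondary-community strengths per band: MDD pre / music / post, HC
  kappa <- list(
    delta = list(MDD = c(pre = 0.70, music = 0.60, post = 0.55), HC = 0.45),
    theta = list(MDD = c(pre = 0.50, music = 0.55, post = 0.55), HC = 0.55),
    alpha = list(MDD = c(pre = 0.50, music = 0.55, post = 0.60), HC = 0.60),
    beta  = list(MDD = c(pre = 0.45, music = 0.50, post = 0.55), HC = 0.70)
  )
  out <- list()
  for (g in c("MDD", "HC")) for (cond in c("pre", "music", "post")) {
    for (b in names(core)) {
      k_sec <- if (effect == "none") 0.6
        else if (g == "HC") kappa[[b]]$HC else kappa[[b]]$MDD[[cond]]
      k_core <- if (effect == "none") 0.6 else 0.85
      out[[paste(g, cond, b, sep = ".")]] <- list(
        coupling_spec(k_core, core[[b]]),
        coupling_spec(k_sec, sec[[b]])
      )
    }
  }
  out
}

#' Simulation configuration for a synthetic cohort
#'
#' @param n_per_group Subjects per group (default 8, the study size).
#' @param sampling_rate Hz (default 500).
#' @param segment_layout Named numeric vector of condition durations in
#'   seconds, in session order (default 60 s pre, 240 s music, 60 s post).
#' @param channel_labels Montage labels (default [retained_channels()]).
#' @param bands List of [band_definition()]s the generator synthesizes
#'   (default [canonical_bands()]).
#' @param band_coupling Named list `"group.condition.band"` -> a
#'   [coupling_spec()] or list thereof (default [default_band_coupling()]).
#' @param band_amplitudes Named amplitudes of each band's contribution,
#'   roughly 1/f-shaped by default.
#' @param noise_sd Broadband white-noise standard deviation in signal
#'   units. The default 1.4 puts the in-band SNR of the dominant delta
#'   band near 10 dB.
#' @param seed Master seed of the cohort's pseudo-random stream.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_per_group = 8,
                              sampling_rate = 500,
                              segment_layout = c(pre = 60, music = 240,
                                                 post = 60),
                              channel_labels = retained_channels(),
                              bands = canonical_bands(),
                              band_coupling = default_band_coupling(),
                              band_amplitudes = c(delta = 1, theta = 0.7,
                                                  alpha = 0.8, beta = 0.5),
                              noise_sd = 1.4,
                              seed = 1L) {
  if (!is_count(n_per_group))
    plv_stop("config", "n_per_group must be a positive integer")
  if (!is_number(sampling_rate) || sampling_rate <= 0)
    plv_stop("config", "sampling_rate must be positive")
  hi <- max(vapply(bands, `[[`, numeric(1), "high"))
  if (sampling_rate <= 2 * hi)
    plv_stop("config",
             "sampling_rate %g must exceed twice the highest band edge %g",
             sampling_rate, hi)
  if (is.null(names(segment_layout)) || any(segment_layout <= 0))
    plv_stop("config", "segment_layout must be named positive durations")
  channel_labels <- as.character(channel_labels)
  if (anyDuplicated(channel_labels))
    plv_stop("config", "channel labels must be unique")
  if (is.null(names(band_amplitudes)) ||
      !setequal(names(band_amplitudes), names(bands)))
    plv_stop("config", "band_amplitudes must be named after the bands")
  for (key in names(band_coupling)) {
    specs <- band_coupling[[key]]
    if (inherits(specs, "coupling_spec")) specs <- list(specs)
    for (sp in specs) {
      if (!inherits(sp, "coupling_spec"))
        plv_stop("config", "band_coupling entry '%s' is not a coupling_spec",
                 key)
      unknown <- setdiff(sp$channels, channel_labels)
      if (length(unknown))
        plv_stop("config", "coupling for '%s' references unknown channel(s): %s",
                 key, paste(unknown, collapse = ", "))
    }
    band_coupling[[key]] <- specs
  }
  structure(list(n_per_group = n_per_group, sampling_rate = sampling_rate,
                 segment_layout = segment_layout,
                 channel_labels = channel_labels, bands = bands,
                 band_coupling = band_coupling,
                 band_amplitudes = band_amplitudes,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config: %d/group, %d channels @ %g Hz, ",
                     "layout %s, seed %d>\n"),
              x$n_per_group, length(x$channel_labels), x$sampling_rate,
              paste(sprintf("%s=%gs", names(x$segment_layout),
                            x$segment_layout), collapse = " "),
              x$seed))
  invisible(x)
}

# --- phase-track machinery --------------------------------------------------

# Smooth random track: Gaussian control points at `rate` Hz,
# spline-interpolated to the sampling grid, standardized to zero mean /
# unit sd. Cheap, deterministic given the seed; the spline keeps the
# track's spectrum essentially below `rate`, so frequency modulation by it
# leaves the carrier band-limited.
smooth_track <- function(n, fs, rate, seed) {
  ncp <- max(4, ceiling(n / fs * rate) + 2)
  cp <- with_seed(seed, stats::rnorm(ncp))
  x <- stats::spline(seq(0, n - 1, length.out = ncp), cp, xout = 0:(n - 1))$y
  (x - mean(x)) / stats::sd(x)
}

# Narrowband wandering phase: random centre frequency in the inner 76% of
# the band plus a smooth frequency deviation (sd = 12% of bandwidth,
# ~1.2 Hz control rate), clipped to the band, integrated to phase. The
# centre-frequency spread is what decorrelates independent channels
# (kappa = 0) within a one-minute segment.
phase_track <- function(n, fs, band, seed) {
  bw <- band$high - band$low
  f0 <- with_seed(derive_seed(seed, 1), stats::runif(1, band$low + 0.12 * bw,
                                                     band$high - 0.12 * bw))
  dev <- 0.12 * bw * smooth_track(n, fs, rate = 1.2,
                                  seed = derive_seed(seed, 2))
  f <- pmin(pmax(f0 + dev, band$low), band$high)
  phi0 <- with_seed(derive_seed(seed, 3), stats::runif(1, -pi, pi))
  phi0 + 2 * pi * cumsum(f) / fs
}

#' Generate a single-channel narrowband signal with known phase
#'
#' Synthesizes `cos(phi(t))` where `phi` is a wandering phase confined to
#' the requested band, and returns both the signal and the ground-truth
#' phase track, so Hilbert phase extraction can be validated against a
#' known answer.
#'
#' @param sampling_rate Hz.
#' @param duration Seconds; `duration * sampling_rate` must be >= 64.
#' @param band A [band_definition()] inside `(0, sampling_rate / 2)`.
#' @param seed Integer seed.
#' @return List with `signal` (numeric vector), `phase` (ground-truth
#'   radians, unwrapped) and `sampling_rate`.
#' @examples
#' s <- make_narrowband_signal(500, 2, canonical_bands()$alpha, seed = 1)
#' @export
make_narrowband_signal <- function(sampling_rate, duration, band, seed = 1L) {
  stopifnot(inherits(band, "band_definition"))
  check_band_vs_rate(band, sampling_rate)
  n <- floor(duration * sampling_rate)
  if (n < 64)
    plv_stop("invalid_input",
             "duration x sampling_rate = %d samples; need at least 64", n)
  phi <- phase_track(n, sampling_rate, band, seed)
  list(signal = cos(phi), phase = phi, sampling_rate = sampling_rate)
}

# Resolve the coupling specs for one (group, condition, band) cell.
coupling_for <- function(config, group, condition, band_name) {
  key <- paste(group, condition, band_name, sep = ".")
  specs <- config$band_coupling[[key]]
  if (is.null(specs))
    plv_stop("config", "no coupling specification for key '%s'", key)
  specs
}

#' Generate one labeled recording with the configured coupling
#'
#' Builds the multichannel signal of one (subject, condition) cell: per
#' band, every coupled channel mixes the band's shared driver phasor at its
#' community strength with an independent narrowband phasor; bands are
#' summed with their amplitudes and broadband Gaussian noise is added.
#'
#' @param config A [simulation_config()].
#' @param group `"MDD"` or `"HC"`.
#' @param condition A condition named in the segment layout.
#' @param subject_seed Integer seed identifying the subject; all tracks are
#'   derived deterministically from it.
#' @param subject_id Optional subject identifier (defaults to the seed).
#' @return A [labeled_recording()].
#' @export
generate_coupled_recording <- function(config, group, condition,
                                       subject_seed,
                                       subject_id = as.character(subject_seed)) {
  stopifnot(inherits(config, "simulation_config"))
  group <- match.arg(group, c("MDD", "HC"))
  if (!condition %in% names(config$segment_layout))
    plv_stop("config", "condition '%s' not in the segment layout", condition)
  fs <- config$sampling_rate
  n <- floor(config$segment_layout[[condition]] * fs)
  labels <- config$channel_labels
  data <- matrix(0, length(labels), n, dimnames = list(labels, NULL))

  for (bn in names(config$bands)) {
    band <- config$bands[[bn]]
    specs <- coupling_for(config, group, condition, bn)
    amp <- config$band_amplitudes[[bn]]
    theta <- phase_track(n, fs, band,
                         derive_seed(subject_seed, condition, bn, "driver"))
    # community membership: first spec that names the channel wins
    for (ci in seq_along(labels)) {
      ch <- labels[ci]
      kappa <- 0
      jit_sd <- 0.15
      for (sp in specs) {
        members <- sp$channels %||% labels
        if (ch %in% members) {
          kappa <- sp$strength
          jit_sd <- sp$phase_jitter_sd
          break
        }
      }
      zeta <- phase_track(n, fs, band,
                          derive_seed(subject_seed, condition, bn, ch, "indep"))
      # channel-specific driver phase offset, stable across conditions
      delta_c <- with_seed(derive_seed(subject_seed, bn, ch, "offset"),
                           stats::runif(1, -pi, pi))
      z <- kappa * exp(1i * (theta + delta_c)) + (1 - kappa) * exp(1i * zeta)
      ph <- Arg(z)
      if (jit_sd > 0)
        ph <- ph + jit_sd * smooth_track(
          n, fs, rate = 8, seed = derive_seed(subject_seed, condition, bn,
                                              ch, "jitter"))
      data[ci, ] <- data[ci, ] + amp * Mod(z) * cos(ph)
    }
  }
  if (config$noise_sd > 0)
    data <- data + config$noise_sd *
      matrix(with_seed(derive_seed(subject_seed, condition, "noise"),
                       stats::rnorm(length(data))),
             nrow(data), ncol(data))
  rec <- eeg_recording(data, fs, labels,
                       meta = list(synthetic = TRUE, group = group,
                                   condition = condition,
                                   subject_seed = subject_seed))
  labeled_recording(rec, subject_id, group, condition)
}

#' Generate a full labeled synthetic cohort
#'
#' Produces one recording per (subject, condition):
#' `n_per_group x 2 groups x length(segment_layout)` recordings in total.
#' Deterministic given the configuration seed; both groups share the
#' session layout, so group differences are encoded purely in the coupling
#' strengths.
#'
#' @param config A [simulation_config()].
#' @return List of [labeled_recording()]s with unique subject ids
#'   (`mdd01..`, `hc01..`).
#' @examples
#' cfg <- simulation_config(n_per_group = 1,
#'                          segment_layout = c(pre = 12, post = 12),
#'                          seed = 42)
#' cohort <- generate_cohort(cfg)
#' length(cohort)  # 1 subject x 2 groups x 2 conditions = 4
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  out <- list()
  for (group in c("MDD", "HC")) {
    for (i in seq_len(config$n_per_group)) {
      sid <- sprintf("%s%02d", tolower(group), i)
      sseed <- derive_seed(config$seed, group, i)
      for (cond in names(config$segment_layout)) {
        out[[paste(sid, cond, sep = ".")]] <-
          generate_coupled_recording(config, group, cond, sseed,
                                     subject_id = sid)
      }
    }
  }
  out
}
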