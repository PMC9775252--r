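# Connectivity: Hilbert-transform instantaneous phase and PLV adjacency
# matrices.

# Analytic signal x + i*H[x] via the frequency-domain construction: double
# the positive frequencies, zero the negative ones (DC and Nyquist kept).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited recording
#'
#' Computes per channel the angle of the analytic signal `x + i H[x]`, where
#' `H` is the Hilbert transform. The input must be narrowband (one output of
#' [decompose_bands()]) for the instantaneous phase to be physically
#' meaningful. Samples within `edge_exclusion` seconds of either end are
#' flagged invalid to guard against filter and Hilbert edge effects.
#'
#' @param recording A band-limited [eeg_recording()].
#' @param edge_exclusion Seconds to mask at each end (default 1).
#' @return An object of class `phase_series`: list with `phases`
#'   (channels x samples matrix in `(-pi, pi]`), `valid_mask` (logical per
#'   sample) and `channel_labels`.
#' @examples
#' t <- seq(0, 2, by = 1 / 500)
#' rec <- eeg_recording(rbind(cos(2 * pi * 10 * t)), 500, "Cz")
#' ph <- instantaneous_phase(rec, edge_exclusion = 0.2)
#' @export
instantaneous_phase <- function(recording, edge_exclusion = 1) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate
  n <- n_samples(recording)
  edge <- floor(edge_exclusion * fs)
  if (n <= 2 * edge)
    plv_stop("too_short",
             "segment of %d samples is too short for %g s edge exclusion",
             n, edge_exclusion)
  degenerate <- apply(recording$data, 1, function(x) stats::sd(x) == 0)
  if (any(degenerate))
    plv_stop("invalid_input",
             "constant (zero-bandwidth) channel(s): %s",
             paste(recording$channel_labels[degenerate], collapse = ", "))
  phases <- t(apply(recording$data, 1, function(x) Arg(analytic_signal(x))))
  rownames(phases) <- recording$channel_labels
  mask <- rep(TRUE, n)
  if (edge > 0) mask[c(seq_len(edge), (n - edge + 1):n)] <- FALSE
  structure(list(phases = phases, valid_mask = mask,
                 channel_labels = recording$channel_labels,
                 sampling_rate = fs),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series: %d channels x %d samples (%d valid)>\n",
              nrow(x$phases), ncol(x$phases), sum(x$valid_mask)))
  invisible(x)
}

#' Phase-locking value of one channel pair
#'
#' The PLV is the modulus of the time-averaged unit phasor of the phase
#' difference: `|<exp(i (phi_x - phi_y))>_t|`, equivalently
#' `sqrt(<cos dphi>^2 + <sin dphi>^2)`. It is 1 for a constant phase
#' relation and 0 for phase differences with no preferred direction.
#'
#' @param phase_x,phase_y Numeric phase vectors in radians, equal length.
#' @param mask Optional logical vector of samples to include.
#' @return PLV in `[0, 1]`.
#' @examples
#' plv_from_phase_pair(rep(0.3, 100), rep(0.3, 100))  # 1
#' @export
plv_from_phase_pair <- function(phase_x, phase_y, mask = NULL) {
  if (length(phase_x) != length(phase_y))
    plv_stop("invalid_input", "phase vectors differ in length (%d vs %d)",
             length(phase_x), length(phase_y))
  if (is.null(mask)) mask <- rep(TRUE, length(phase_x))
  if (sum(mask) < 2)
    plv_stop("invalid_input", "need at least 2 valid samples, got %d",
             sum(mask))
  d <- phase_x[mask] - phase_y[mask]
  sqrt(mean(cos(d))^2 + mean(sin(d))^2)
}

#' PLV adjacency matrix
#'
#' Computes the full symmetric PLV matrix over all channel pairs of a
#' `phase_series`. The diagonal is set to 1 exactly (a channel is perfectly
#' synchronized with itself).
#'
#' @param phases A `phase_series` from [instantaneous_phase()].
#' @param band Optional [band_definition()] recorded as provenance.
#' @param condition,subject_id,group Optional provenance strings.
#' @return An object of class `connectivity_matrix`: list with `values`
#'   (channels x channels PLV matrix), `channel_labels`, `n_samples` (number
#'   of averaged samples) and the provenance fields.
#' @export
plv_matrix <- function(phases, band = NULL, condition = NULL,
                       subject_id = NULL, group = NULL) {
  stopifnot(inherits(phases, "phase_series"))
  if (nrow(phases$phases) < 2)
    plv_stop("invalid_input", "need at least 2 channels")
  P <- phases$phases[, phases$valid_mask, drop = FALSE]
  s <- ncol(P)
  E <- exp(1i * P)
  V <- Mod(E %*% Conj(t(E))) / s
  diag(V) <- 1
  V <- (V + t(V)) / 2  # enforce exact symmetry against rounding
  dimnames(V) <- list(phases$channel_labels, phases$channel_labels)
  structure(list(values = V, channel_labels = phases$channel_labels,
                 band = band, condition = condition, subject_id = subject_id,
                 group = group, n_samples = s),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix %s/%s/%s: %d channels, S = %d>\n",
              x$subject_id %||% "?", x$condition %||% "?",
              if (is.null(x$band)) "?" else x$band$name,
              length(x$channel_labels), x$n_samples))
  invisible(x)
}

#' PLV matrices for a whole cohort
#'
#' Runs the standard chain (channel selection, common average reference,
#' broadband filter, band decomposition, instantaneous phase, PLV) on every
#' labeled recording of the requested conditions.
#'
#' @param cohort List of [labeled_recording()]s, one per
#'   (subject, condition).
#' @param bands List of [band_definition()]s (default [canonical_bands()]).
#' @param conditions Conditions to analyze (default `c("pre", "post")`;
#'   the music segment is carried but not analyzed).
#' @param edge_exclusion Seconds masked at segment edges (default 1).
#' @param broadband Length-2 numeric, edges of the broadband pre-filter.
#' @return List of [plv_matrix()] results, one per
#'   (subject, condition, band).
#' @export
cohort_connectivity <- function(cohort, bands = canonical_bands(),
                                conditions = c("pre", "post"),
                                edge_exclusion = 1,
                                broadband = c(0.1, 30)) {
  keep <- vapply(cohort, function(r) r$condition %in% conditions, logical(1))
  out <- list()
  for (lr in cohort[keep]) {
    rec <- preprocess_recording(lr$recording, low = broadband[1],
                                high = broadband[2])
    per_band <- decompose_bands(rec, bands)
    for (bn in names(per_band)) {
      ph <- instantaneous_phase(per_band[[bn]], edge_exclusion)
      m <- plv_matrix(ph, band = bands[[bn]], condition = lr$condition,
                      subject_id = lr$subject_id, group = lr$group)
      out[[paste(lr$subject_id, lr$condition, bn, sep = ".")]] <- m
    }
  }
  out
}

#' Group-averaged connectivity matrices
#'
#' Averages PLV matrices elementwise within each (group, condition, band)
#' cell, the quantity displayed as per-state correlation-matrix panels.
#'
#' @param matrices List of `connectivity_matrix` objects with `group` set.
#' @return Named list (`group.condition.band` -> numeric matrix).
#' @export
average_connectivity <- function(matrices) {
  keys <- vapply(matrices, function(m)
    paste(m$group, m$condition, m$band$name, sep = "."), character(1))
  out <- list()
  for (k in unique(keys)) {
    ms <- matrices[keys == k]
    out[[k]] <- Reduce(`+`, lapply(ms, `[[`, "values")) / length(ms)
  }
  out
}
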