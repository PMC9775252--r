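# Preprocessing: zero-phase FIR band filtering, common average reference,
# channel selection, condition segmentation and band decomposition.

#' The 19 retained 10-20 montage channels
#'
#' Scalp channels kept for whole-head connectivity analysis, in their
#' canonical order.
#'
#' @return Character vector of 19 labels.
#' @export
retained_channels <- function() {
  c("Fp1", "Fp2", "Fpz", "F3", "F4", "F7", "F8", "Cz", "C3", "C4",
    "T7", "T8", "Pz", "P3", "P4", "P7", "P8", "O1", "O2")
}

# --- FIR design -------------------------------------------------------------

# Hamming-windowed sinc bandpass. The transition width is 25% of the lower
# band edge with a 1 Hz floor, which keeps the filter length bounded for
# sub-hertz edges (a 0.1 Hz edge would otherwise need tens of seconds of
# data). Hamming gives ~53 dB stop-band attenuation per pass; the filter is
# applied forward-backward so the effective attenuation doubles and the net
# phase response is exactly zero.
fir_bandpass_taps <- function(low, high, sampling_rate) {
  trans <- max(1, 0.25 * low)
  ntaps <- ceiling(3.3 * sampling_rate / trans)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1  # type-I symmetric
  m <- (ntaps - 1) / 2
  n <- seq_len(ntaps) - 1 - m
  wl <- 2 * pi * low / sampling_rate
  wh <- 2 * pi * high / sampling_rate
  h <- ifelse(n == 0, (wh - wl) / pi, (sin(wh * n) - sin(wl * n)) / (pi * n))
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(ntaps - 1)) / (ntaps - 1))
  h <- h * w
  # normalize to unit gain at the passband centre (geometric mean frequency)
  fc <- sqrt(low * high)
  gain <- Mod(sum(h * exp(-2i * pi * fc / sampling_rate * (0:(ntaps - 1)))))
  h / gain
}

# Zero-phase filtering of one signal vector: forward-backward application of
# a symmetric FIR equals a single convolution with conv(h, rev(h)), applied
# with group-delay compensation. Edges are odd-reflection padded (filtfilt
# convention) and the convolution runs through the FFT.
filtfilt_fir <- function(x, h) {
  ntaps <- length(h)
  g <- stats::convolve(h, rev(h), type = "open")  # length 2*ntaps - 1
  delay <- ntaps - 1
  n <- length(x)
  pad <- min(n - 1, 3 * ntaps)
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[n] - x[seq(n - 1, n - pad)]
  xp <- c(left, x, right)
  np <- length(xp)
  nfft <- stats::nextn(np + length(g) - 1, 2)
  y <- Re(stats::fft(stats::fft(c(xp, numeric(nfft - np))) *
                       stats::fft(c(g, numeric(nfft - length(g)))),
                     inverse = TRUE)) / nfft
  y[(delay + pad + 1):(delay + pad + n)]
}

#' Zero-phase FIR bandpass filter
#'
#' Filters every channel with a Hamming-windowed FIR applied
#' forward-backward, so the output has zero phase distortion. The filter
#' order follows from a transition width of 25% of the lower edge
#' (minimum 1 Hz).
#'
#' @param recording An [eeg_recording()].
#' @param low,high Passband edges in Hz; must satisfy
#'   `0 < low < high < sampling_rate / 2`.
#' @return A filtered `eeg_recording` with the same shape and labels.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(19 * 5000), 19), 500, retained_channels())
#' filt <- bandpass_filter(rec, 0.1, 30)
#' @export
bandpass_filter <- function(recording, low, high) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate
  if (!is_number(low) || !is_number(high) || low <= 0 || high <= low ||
      high >= fs / 2)
    plv_stop("invalid_band",
             "passband (%s, %s) Hz invalid for sampling rate %g Hz",
             format(low), format(high), fs)
  h <- fir_bandpass_taps(low, high, fs)
  if (n_samples(recording) < 3 * length(h))
    plv_stop("too_short",
             "recording has %d samples but the %d-tap filter needs at least %d",
             n_samples(recording), length(h), 3 * length(h))
  out <- recording
  out$data <- t(apply(recording$data, 1, filtfilt_fir, h = h))
  rownames(out$data) <- recording$channel_labels
  out$meta$filter <- c(low = low, high = high, ntaps = length(h))
  out
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the channel mean of the output is zero at every sample.
#'
#' @param recording An [eeg_recording()] with at least two channels.
#' @return Re-referenced `eeg_recording`.
#' @export
common_average_reference <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (n_channels(recording) < 2)
    plv_stop("invalid_input",
             "common average reference needs at least 2 channels")
  out <- recording
  out$data <- sweep(recording$data, 2, colMeans(recording$data))
  out$meta$reference <- "common_average"
  out
}

#' Select and reorder channels
#'
#' @param recording An [eeg_recording()].
#' @param keep Ordered character vector of labels to retain; defaults to the
#'   19 channels of [retained_channels()].
#' @return An `eeg_recording` whose rows are `keep`, in order.
#' @export
select_channels <- function(recording, keep = retained_channels()) {
  stopifnot(inherits(recording, "eeg_recording"))
  missing <- setdiff(keep, recording$channel_labels)
  if (length(missing))
    plv_stop("missing_channel", "channel(s) not present in recording: %s",
             paste(missing, collapse = ", "))
  out <- recording
  out$data <- recording$data[keep, , drop = FALSE]
  out$channel_labels <- keep
  out
}

#' Split a session recording into condition segments
#'
#' Cuts the recording into contiguous, non-overlapping, half-open segments
#' following the session layout (default 1 min pre-stimulus rest, 4 min
#' musical stimulation, 1 min post-stimulus rest).
#'
#' @param recording An [eeg_recording()] holding one full session.
#' @param layout Named numeric vector of durations in seconds, in session
#'   order; names are condition labels.
#' @return List of `condition_segment` objects, each with fields
#'   `recording`, `condition`, `start` (seconds) and `duration`.
#' @export
segment_conditions <- function(recording,
                               layout = c(pre = 60, music = 240, post = 60)) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (is.null(names(layout)) || any(!nzchar(names(layout))))
    plv_stop("invalid_input", "layout must be a named vector of durations")
  if (any(layout <= 0))
    plv_stop("invalid_input", "all segment durations must be positive")
  fs <- recording$sampling_rate
  counts <- floor(layout * fs)
  if (sum(counts) > n_samples(recording))
    plv_stop("insufficient_data",
             "layout needs %d samples but the recording has %d",
             sum(counts), n_samples(recording))
  start <- 0L
  out <- vector("list", length(layout))
  for (i in seq_along(layout)) {
    idx <- (start + 1):(start + counts[i])  # half-open: boundary sample
    seg <- recording                        # belongs to the later segment
    seg$data <- recording$data[, idx, drop = FALSE]
    out[[i]] <- structure(list(recording = seg,
                               condition = names(layout)[i],
                               start = start / fs,
                               duration = unname(layout[i])),
                          class = "condition_segment")
    start <- start + counts[i]
  }
  out
}

#' @export
print.condition_segment <- function(x, ...) {
  cat(sprintf("<condition_segment '%s' @ %.1f s, %.1f s long>\n",
              x$condition, x$start, x$duration))
  invisible(x)
}

#' Decompose a signal into frequency bands
#'
#' Applies [bandpass_filter()] once per band.
#'
#' @param x An [eeg_recording()] or `condition_segment`.
#' @param bands List of [band_definition()]s, e.g. [canonical_bands()].
#' @return Named list (band name -> band-limited `eeg_recording`).
#' @export
decompose_bands <- function(x, bands = canonical_bands()) {
  rec <- if (inherits(x, "condition_segment")) x$recording else x
  stopifnot(inherits(rec, "eeg_recording"))
  out <- list()
  for (b in bands) {
    check_band_vs_rate(b, rec$sampling_rate)
    out[[b$name]] <- bandpass_filter(rec, b$low, b$high)
  }
  out
}

#' Standard preprocessing chain for one recording
#'
#' Channel selection, common average reference over the retained channels,
#' then a broadband zero-phase FIR bandpass (default 0.1-30 Hz).
#'
#' @param recording An [eeg_recording()].
#' @param keep Channels to retain (default [retained_channels()]).
#' @param low,high Broadband filter edges in Hz.
#' @return Preprocessed `eeg_recording`.
#' @export
preprocess_recording <- function(recording, keep = retained_channels(),
                                 low = 0.1, high = 30) {
  keep <- intersect_or_all(keep, recording)
  rec <- select_channels(recording, keep)
  rec <- common_average_reference(rec)
  bandpass_filter(rec, low, high)
}

# Allow preprocessing of synthetic recordings that already carry exactly the
# retained montage (or a test-sized subset): if the recording's labels are a
# subset of `keep`, keep them all in recording order.
intersect_or_all <- function(keep, recording) {
  if (all(recording$channel_labels %in% keep)) recording$channel_labels
  else keep
}
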