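# The EEG recording container: channels x samples matrix with a sampling
# rate and ordered montage labels.

#' Create an EEG recording
#'
#' The basic signal container of the package: a channels x samples numeric
#' matrix with a sampling rate and ordered 10-20 montage labels. Synthetic
#' signals are unitless; recordings read from EDF carry the file's physical
#' units in `meta`.
#'
#' @param data Numeric matrix, one row per channel.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector of unique montage labels, one per
#'   row of `data`.
#' @param meta Free-form provenance list (subject id, source file, ...).
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(200), 2), 100, c("C3", "C4"))
#' n_samples(rec)
#' @export
eeg_recording <- function(data, sampling_rate, channel_labels,
                          meta = list()) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is_number(sampling_rate) || sampling_rate <= 0)
    plv_stop("invalid_input", "sampling_rate must be a positive number")
  channel_labels <- as.character(channel_labels)
  if (nrow(data) != length(channel_labels))
    plv_stop("invalid_input",
             "data has %d rows but %d channel labels were given",
             nrow(data), length(channel_labels))
  if (anyDuplicated(channel_labels))
    plv_stop("invalid_input", "channel labels must be unique")
  if (!all(is.finite(data)))
    plv_stop("invalid_input", "recording contains non-finite samples")
  rownames(data) <- channel_labels
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_labels = channel_labels, meta = meta),
            class = "eeg_recording")
}

#' @rdname eeg_recording
#' @param x An `eeg_recording`.
#' @export
n_channels <- function(x) nrow(x$data)

#' @rdname eeg_recording
#' @export
n_samples <- function(x) ncol(x$data)

#' @rdname eeg_recording
#' @export
recording_duration <- function(x) ncol(x$data) / x$sampling_rate

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording: %d channels x %d samples @ %g Hz (%.1f s)>\n",
              n_channels(x), n_samples(x), x$sampling_rate,
              recording_duration(x)))
  cat(" channels:", paste(utils::head(x$channel_labels, 8), collapse = " "),
      if (n_channels(x) > 8) "..." else "", "\n")
  invisible(x)
}

#' Attach cohort labels to a recording
#'
#' Wraps a recording with its subject identifier, diagnostic group and
#' session condition, the unit handled by cohort-level operations.
#'
#' @param recording An [eeg_recording()].
#' @param subject_id Subject identifier string.
#' @param group One of `"MDD"` or `"HC"`.
#' @param condition One of `"pre"`, `"music"` or `"post"`.
#' @return An object of class `labeled_recording`.
#' @export
labeled_recording <- function(recording, subject_id, group, condition) {
  stopifnot(inherits(recording, "eeg_recording"))
  group <- match.arg(group, c("MDD", "HC"))
  condition <- match.arg(condition, c("pre", "music", "post"))
  structure(list(recording = recording,
                 subject_id = as.character(subject_id),
                 group = group, condition = condition),
            class = "labeled_recording")
}

#' @export
print.labeled_recording <- function(x, ...) {
  cat(sprintf("<labeled_recording %s [%s, %s]>\n", x$subject_id, x$group,
              x$condition))
  print(x$recording)
  invisible(x)
}
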