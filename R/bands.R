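# Frequency band definitions.

#' Define a frequency band
#'
#' A band is a named half-open frequency interval used for FIR band
#' decomposition and per-band connectivity analysis.
#'
#' @param name Band name, e.g. `"alpha"`.
#' @param low Lower edge in Hz, strictly positive.
#' @param high Upper edge in Hz, strictly greater than `low`.
#' @return An object of class `band_definition`.
#' @examples
#' band_definition("alpha", 8, 13)
#' @export
band_definition <- function(name, low, high) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    plv_stop("invalid_band", "band name must be a non-empty string")
  if (!is_number(low) || !is_number(high) || low <= 0 || high <= low)
    plv_stop("invalid_band", "band edges must satisfy 0 < low < high (got %s, %s)",
             format(low), format(high))
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' Canonical EEG frequency bands
#'
#' The four bands used throughout the pipeline: delta (0.5-4 Hz),
#' theta (4-8 Hz), alpha (8-13 Hz) and beta (13-30 Hz).
#'
#' @param names Optional character vector selecting a subset.
#' @return Named list of [band_definition()] objects.
#' @export
canonical_bands <- function(names = c("delta", "theta", "alpha", "beta")) {
  all <- list(
    delta = band_definition("delta", 0.5, 4),
    theta = band_definition("theta", 4, 8),
    alpha = band_definition("alpha", 8, 13),
    beta  = band_definition("beta", 13, 30)
  )
  missing <- setdiff(names, names(all))
  if (length(missing))
    plv_stop("invalid_band", "unknown canonical band(s): %s",
             paste(missing, collapse = ", "))
  all[names]
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz>\n", x$name, x$low, x$high))
  invisible(x)
}

# Band must sit strictly inside (0, Nyquist) for the given sampling rate.
check_band_vs_rate <- function(band, sampling_rate) {
  if (band$high >= sampling_rate / 2)
    plv_stop("invalid_band",
             "band %s (%g-%g Hz) exceeds Nyquist frequency %g Hz",
             band$name, band$low, band$high, sampling_rate / 2)
  invisible(band)
}
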