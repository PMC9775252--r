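# File formats: delimited-text recordings, a minimal EDF reader/writer,
# connectivity matrix CSV / long TSV, cohort manifests.

#' Write / read a recording as delimited text
#'
#' Samples are rows, channels are columns, with a one-line channel-label
#' header. Values are written with 17 significant digits so a write/read
#' round trip reproduces the doubles exactly.
#'
#' @param recording An [eeg_recording()].
#' @param path Output file.
#' @param sep Field separator (default `","`).
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns an `eeg_recording`.
#' @export
write_recording_csv <- function(recording, path, sep = ",") {
  stopifnot(inherits(recording, "eeg_recording"))
  con <- file(path, "wb")  # binary mode: "\n" endings on every platform
  on.exit(close(con))
  writeLines(paste(recording$channel_labels, collapse = sep), con)
  m <- t(recording$data)
  lines <- apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = sep))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param sampling_rate Sampling rate in Hz (not stored in the text format).
#' @export
read_recording_csv <- function(path, sampling_rate, sep = ",") {
  if (!file.exists(path))
    plv_stop("missing_file", "file not found: %s", path)
  header <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  m <- utils::read.table(path, sep = sep, skip = 1,
                         colClasses = "numeric")
  eeg_recording(t(as.matrix(m)), sampling_rate, trimws(header),
                meta = list(source = path))
}

# --- EDF --------------------------------------------------------------------
# Minimal EDF implementation: 16-bit samples, one-second data records,
# standard 256-byte header plus 256 bytes per signal. Covers what the
# pipeline writes; not a general-purpose EDF library.

pad <- function(x, n) formatC(as.character(x), width = -n)

#' Write / read an EDF file
#'
#' Writes a recording as 16-bit EDF with one-second data records. Samples
#' are linearly quantized per channel between the channel's physical
#' extrema, so a round trip is exact to about `range / 65534`. Durations
#' are truncated to whole seconds.
#'
#' @param recording An [eeg_recording()].
#' @param path Output file.
#' @param patient,recording_id Free-text header fields.
#' @return `write_edf` returns `path` invisibly; `read_edf` returns an
#'   `eeg_recording`.
#' @export
write_edf <- function(recording, path, patient = "X", recording_id = "X") {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sampling_rate
  if (fs != round(fs))
    plv_stop("invalid_input", "EDF writer needs an integer sampling rate")
  n_rec <- floor(n_samples(recording) / fs)
  if (n_rec < 1)
    plv_stop("invalid_input", "recording shorter than one EDF data record")
  ns <- n_channels(recording)
  data <- recording$data[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ == 0
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad(patient, 80), pad(recording_id, 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (1 + ns), 8), pad("", 44), pad(n_rec, 8), pad(1, 8), pad(ns, 4),
    paste(pad(recording$channel_labels, 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(pad(sprintf("%.6g", pmin_), 8), collapse = ""),
    paste(pad(sprintf("%.6g", pmax_), 8), collapse = ""),
    paste(rep(pad(dmin, 8), ns), collapse = ""),
    paste(rep(pad(dmax, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(fs, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  # physical -> digital, rounding to nearest integer
  pm_read <- as.numeric(sprintf("%.6g", pmin_))   # quantize like the header
  px_read <- as.numeric(sprintf("%.6g", pmax_))
  scale_ <- (dmax - dmin) / (px_read - pm_read)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((data[ch, idx] - pm_read[ch]) * scale_[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  if (!file.exists(path))
    plv_stop("missing_file", "file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)  # transducer
  for (i in seq_len(ns)) rd(8)   # dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)  # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, signed = TRUE,
                     endian = "little")
      phys <- pmin_[ch] + (dig - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
      data[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  eeg_recording(data, spr[1] / rec_dur, labels, meta = list(source = path))
}

# --- connectivity matrices --------------------------------------------------

#' Write / read a connectivity matrix as CSV
#'
#' Channel labels form the header row and the first column. Values carry
#' 17 significant digits (exact double round trip).
#'
#' @param matrix A `connectivity_matrix` or plain numeric matrix.
#' @param path Output file.
#' @return `write_connectivity_csv` returns `path` invisibly;
#'   `read_connectivity_csv` returns a numeric matrix with dimnames.
#' @export
write_connectivity_csv <- function(matrix, path) {
  V <- if (inherits(matrix, "connectivity_matrix")) matrix$values
       else as.matrix(matrix)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste(c("", colnames(V)), collapse = ","), con)
  writeLines(vapply(seq_len(nrow(V)), function(i)
    paste(c(rownames(V)[i], sprintf("%.17g", V[i, ])), collapse = ","),
    character(1)), con)
  invisible(path)
}

#' @rdname write_connectivity_csv
#' @export
read_connectivity_csv <- function(path) {
  if (!file.exists(path))
    plv_stop("missing_file", "file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Long-format connectivity table
#'
#' Flattens a list of connectivity matrices into one row per unordered
#' channel pair with full provenance; the standard exchange format for a
#' cohort's PLV values.
#'
#' @param matrices List of `connectivity_matrix` objects.
#' @return Data frame: subject_id, group, condition, band, ch1, ch2, plv.
#' @export
connectivity_long <- function(matrices) {
  rows <- lapply(matrices, function(m) {
    V <- m$values
    ut <- which(upper.tri(V), arr.ind = TRUE)
    data.frame(subject_id = m$subject_id %||% NA_character_,
               group = m$group %||% NA_character_,
               condition = m$condition %||% NA_character_,
               band = if (is.null(m$band)) NA_character_ else m$band$name,
               ch1 = rownames(V)[ut[, 1]], ch2 = colnames(V)[ut[, 2]],
               plv = V[ut], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a binary graph as an edge-list TSV
#'
#' @param graph A `binary_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path) {
  stopifnot(inherits(graph, "binary_graph"))
  A <- graph$adjacency
  ut <- which(upper.tri(A) & A, arr.ind = TRUE)
  df <- data.frame(label1 = rownames(A)[ut[, 1]],
                   label2 = colnames(A)[ut[, 2]])
  write_tsv(df, path)
  invisible(path)
}

# Deterministic TSV writer ("\n" endings, no quoting, fixed na string).
write_tsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (is.null(df) || !nrow(df)) {
    writeLines(paste(names(df), collapse = "\t"), con)
    return(invisible(path))
  }
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  invisible(path)
}

#' Write a synthetic cohort to disk with a manifest
#'
#' One file per (subject, condition) in EDF or delimited-text format plus
#' a JSON manifest listing subject id, group, condition, file and seed.
#'
#' @param cohort List of [labeled_recording()]s (from [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (default, lossless) or `"edf"` (16-bit quantized).
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(cohort, function(lr) {
    fname <- sprintf("%s_%s.%s", lr$subject_id, lr$condition, format)
    fpath <- file.path(dir, fname)
    if (format == "edf") write_edf(lr$recording, fpath)
    else write_recording_csv(lr$recording, fpath)
    list(subject_id = lr$subject_id, group = lr$group,
         condition = lr$condition, file = fname,
         sampling_rate = lr$recording$sampling_rate,
         seed = lr$recording$meta$subject_seed %||% NA)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(unname(entries), manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding the manifest and data files.
#' @return List of [labeled_recording()]s.
#' @export
read_cohort <- function(dir) {
  manifest <- file.path(dir, "manifest.json")
  if (!file.exists(manifest))
    plv_stop("missing_file", "expected manifest at %s", manifest)
  entries <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  lapply(entries, function(e) {
    fpath <- file.path(dir, e$file)
    rec <- if (grepl("\\.edf$", e$file)) read_edf(fpath)
           else read_recording_csv(fpath, e$sampling_rate)
    labeled_recording(rec, e$subject_id, e$group, e$condition)
  })
}
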