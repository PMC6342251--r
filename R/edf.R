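# Minimal EDF/EDF+ reader and writer.
#
# EDF is a fixed-layout format: a 256-byte ASCII global header, 256 ASCII
# bytes per signal, then data records of 16-bit little-endian integers.
# Only continuous recordings with a homogeneous EEG sampling rate are
# supported; annotation and non-EEG auxiliary signals are dropped.

edf_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read an EDF/EDF+ file into a Recording
#'
#' @param path EDF file path.
#' @return list with `data` (channels x samples matrix, physical units),
#'   `fs`, `channel_ids`, `meta` and `dropped` (labels of non-EEG signals
#'   that were discarded).
#' @keywords internal
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  version <- edf_ascii(con, 8L)
  if (!nzchar(version)) stop("unreadable EDF file (empty header): ", path)
  patient <- edf_ascii(con, 80L)
  recording_id <- edf_ascii(con, 80L)
  startdate <- edf_ascii(con, 8L)
  starttime <- edf_ascii(con, 8L)
  header_bytes <- as.integer(edf_ascii(con, 8L))
  reserved <- edf_ascii(con, 44L)
  n_records <- as.integer(edf_ascii(con, 8L))
  record_dur <- as.numeric(edf_ascii(con, 8L))
  ns <- as.integer(edf_ascii(con, 4L))
  if (is.na(ns) || ns < 1L) stop("EDF format error: no signals declared")
  fld <- function(n) vapply(seq_len(ns), function(i) edf_ascii(con, n), "")
  labels <- fld(16L); transducer <- fld(80L); phys_dim <- fld(8L)
  phys_min <- as.numeric(fld(8L)); phys_max <- as.numeric(fld(8L))
  dig_min <- as.numeric(fld(8L)); dig_max <- as.numeric(fld(8L))
  prefilter <- fld(80L)
  nsamp <- as.integer(fld(8L))
  invisible(readBin(con, "raw", 32L * ns))     # per-signal reserved
  if (is.na(n_records) || n_records < 0L) stop("EDF format error: bad record count")

  is_annot <- grepl("annotation", labels, ignore.case = TRUE)
  # EEG signals: same sample count per record as the modal EEG rate and a
  # voltage-like physical dimension
  volt <- grepl("v", phys_dim, ignore.case = TRUE) | phys_dim == ""
  eeg <- !is_annot & volt
  if (!any(eeg)) stop("EDF format error: no EEG channels in ", path)
  main_nsamp <- as.integer(names(sort(table(nsamp[eeg]), decreasing = TRUE))[1])
  eeg <- eeg & nsamp == main_nsamp
  dropped <- labels[!eeg]
  if (length(dropped))
    warning("dropping non-EEG/auxiliary signal(s): ", paste(dropped, collapse = ", "))

  rec_words <- sum(nsamp)
  raw <- readBin(con, "integer", n = rec_words * n_records, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < rec_words * n_records) stop("EDF I/O error: truncated data in ", path)
  offsets <- c(0L, cumsum(nsamp))
  idx_eeg <- which(eeg)
  data <- matrix(0, nrow = length(idx_eeg), ncol = main_nsamp * n_records)
  for (k in seq_along(idx_eeg)) {
    i <- idx_eeg[k]
    sel <- as.vector(outer(seq_len(nsamp[i]) + offsets[i],
                           (seq_len(n_records) - 1L) * rec_words, `+`))
    dig <- raw[sel]
    scale <- (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
    data[k, ] <- (dig - dig_min[i]) * scale + phys_min[i]
  }
  fs <- main_nsamp / record_dur
  list(data = data, fs = fs, channel_ids = labels[idx_eeg],
       meta = list(source = path, patient = patient, recording_id = recording_id,
                   startdate = startdate, starttime = starttime),
       dropped = dropped)
}

edf_pad <- function(x, n) {
  s <- substr(format(x, scientific = FALSE, trim = TRUE), 1L, n)
  formatC(s, width = n, flag = "-")
}

#' Write a Recording to an EDF file
#'
#' 16-bit EDF with one-second data records; physical range taken from the
#' data (symmetric, padded 5%). Lossy to EDF's 16-bit quantization.
#'
#' @param rec an `eeg_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nch <- nrow(rec$data)
  n_records <- floor(ncol(rec$data) / fs)
  if (n_records < 1L) stop("recording shorter than one EDF record (1 s)")
  X <- rec$data[, seq_len(n_records * fs), drop = FALSE]
  amax <- max(1, max(abs(X), na.rm = TRUE)) * 1.05
  phys_min <- -amax; phys_max <- amax
  dig_min <- -32768; dig_max <- 32767
  dig <- round((X - phys_min) / (phys_max - phys_min) * (dig_max - dig_min) + dig_min)
  dig[!is.finite(dig)] <- 0
  dig <- pmin(pmax(dig, dig_min), dig_max)   # dig first: keeps matrix dims

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8L),
    edf_pad("X X X X", 80L),
    edf_pad(sprintf("Startdate 01-JAN-2000 synthetic PMA=%s",
                    rec$pma_weeks %||% "NA"), 80L),
    edf_pad("01.01.00", 8L), edf_pad("00.00.00", 8L),
    edf_pad(as.character(256L + 256L * nch), 8L),
    edf_pad("", 44L),
    edf_pad(as.character(n_records), 8L),
    edf_pad("1", 8L),
    edf_pad(as.character(nch), 4L))
  sig <- paste0(
    paste(edf_pad(rec$channel_ids, 16L), collapse = ""),
    paste(edf_pad(rep("", nch), 80L), collapse = ""),
    paste(edf_pad(rep("uV", nch), 8L), collapse = ""),
    paste(edf_pad(rep(sprintf("%.2f", phys_min), nch), 8L), collapse = ""),
    paste(edf_pad(rep(sprintf("%.2f", phys_max), nch), 8L), collapse = ""),
    paste(edf_pad(rep(as.character(dig_min), nch), 8L), collapse = ""),
    paste(edf_pad(rep(as.character(dig_max), nch), 8L), collapse = ""),
    paste(edf_pad(rep("BP:1-40Hz N:50Hz", nch), 80L), collapse = ""),
    paste(edf_pad(rep(as.character(fs), nch), 8L), collapse = ""),
    paste(edf_pad(rep("", nch), 32L), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  for (r in seq_len(n_records)) {
    block <- t(dig[, ((r - 1L) * fs + 1L):(r * fs), drop = FALSE])
    writeBin(as.integer(block), con, size = 2L, endian = "little")
  }
  invisible(path)
}
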