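# The Recording container: a multichannel EEG matrix with metadata.

#' Construct an EEG recording object
#'
#' A thin validated container for multichannel EEG: a channels-by-samples
#' numeric matrix in microvolts, a sampling rate, channel labels (10-20
#' names such as Fp1, C3), and an optional postmenstrual age in weeks.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate, Hz (> 0).
#' @param channel_ids character vector of channel labels, one per row.
#' @param pma_weeks postmenstrual age in weeks, or `NULL`.
#' @param meta free-form provenance list.
#' @param validate check invariants (finite data, equal-length channels).
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_ids = NULL, pma_weeks = NULL,
                          meta = list(), validate = TRUE) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  if (!is.matrix(data) || !is.numeric(data)) stop("data must be a numeric matrix")
  if (is.null(channel_ids)) channel_ids <- paste0("CH", seq_len(nrow(data)))
  if (validate) {
    if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
    if (nrow(data) < 1L) stop("recording must have at least one channel")
    if (length(channel_ids) != nrow(data)) stop("one channel id per data row required")
  }
  structure(list(data = data, fs = as.numeric(fs),
                 channel_ids = as.character(channel_ids),
                 pma_weeks = pma_weeks, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channel(s) x %d samples @ %.4g Hz (%.1f min)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs / 60))
  cat("  channels:", paste(x$channel_ids, collapse = ", "), "\n")
  if (!is.null(x$pma_weeks)) cat(sprintf("  PMA: %.1f weeks\n", x$pma_weeks))
  invisible(x)
}

#' Number of samples / duration of a recording
#' @param rec an `eeg_recording`.
#' @return integer sample count or duration in seconds.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' Extract a time slice of a recording
#'
#' Half-open slice `[start_s, end_s)` in seconds from recording start.
#'
#' @param rec an `eeg_recording`.
#' @param start_s,end_s slice bounds in seconds.
#' @return an `eeg_recording` covering the requested span.
#' @export
slice_recording <- function(rec, start_s, end_s) {
  i0 <- max(1L, as.integer(floor(start_s * rec$fs)) + 1L)
  i1 <- min(ncol(rec$data), as.integer(ceiling(end_s * rec$fs)))
  if (i1 < i0) stop("empty slice requested")
  eeg_recording(rec$data[, i0:i1, drop = FALSE], rec$fs, rec$channel_ids,
                rec$pma_weeks, rec$meta, validate = FALSE)
}
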