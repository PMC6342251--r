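# Reading recordings and the pre-processing front end: 1-40 Hz band-pass,
# 50 Hz notch, bad-channel discard, decimation.

#' Read an EEG recording
#'
#' Reads EDF/EDF+ (non-EEG auxiliary and annotation channels dropped with a
#' warning) or a CSV matrix (one column per channel, header row of channel
#' labels; sampling rate and PMA from an optional `<path>.json` sidecar or
#' the `fs` / `pma_weeks` arguments).
#'
#' @param path input file.
#' @param format `"edf"` or `"csv"`; guessed from the extension by default.
#' @param fs sampling rate for CSV input (overrides sidecar).
#' @param pma_weeks postmenstrual age, weeks (optional).
#' @return an `eeg_recording` in microvolts at the file's native rate.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           fs = NULL, pma_weeks = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read recording: file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "edf") {
    e <- read_edf(path)
    pma <- pma_weeks
    if (is.null(pma)) {
      m <- regmatches(e$meta$recording_id,
                      regexpr("PMA=([0-9.]+)", e$meta$recording_id))
      if (length(m)) pma <- as.numeric(sub("PMA=", "", m))
    }
    return(eeg_recording(e$data, e$fs, e$channel_ids, pma, e$meta))
  }
  sidecar <- paste0(path, ".json")
  side <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  df <- utils::read.csv(path, check.names = FALSE)
  if (!ncol(df)) stop("recording format error: no channels in ", path)
  fs <- fs %||% side$fs
  if (is.null(fs)) stop("CSV recordings need a sampling rate (fs argument or JSON sidecar)")
  eeg_recording(t(as.matrix(df)), fs, names(df),
                pma_weeks %||% side$pma_weeks, list(source = path))
}

# RBJ-style IIR notch biquad (quality factor Q), coefficients (b, a).
design_notch <- function(notch_hz, fs, Q = 30) {
  w0 <- 2 * pi * notch_hz / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Band-pass and notch filter a recording
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass plus a
#' 2nd-order IIR notch (Q = 30). The band-pass removes DC, so the output is
#' zero-mean per channel - a property the ASR derivation relies on.
#'
#' @param rec an `eeg_recording`.
#' @param low_hz,high_hz band edges, Hz (defaults 1 and 40).
#' @param notch_hz mains frequency to notch out (default 50); `NULL` skips
#'   the notch.
#' @param order Butterworth order (of the analogue prototype; default 4).
#' @return filtered copy of `rec`.
#' @export
bandpass_notch <- function(rec, low_hz = 1, high_hz = 40, notch_hz = 50,
                           order = 4) {
  if (rec$fs <= 2 * high_hz)
    stop("sampling rate too low for the requested band (need fs > 2*high_hz)")
  bp <- signal::butter(order, c(low_hz, high_hz) / (rec$fs / 2), type = "pass")
  if (!is.null(notch_hz) && notch_hz < rec$fs / 2) {
    # cascade band-pass and notch into one transfer function (polynomial
    # product) so each channel needs a single forward-backward pass
    nf <- design_notch(notch_hz, rec$fs)
    b <- convolve(bp$b, rev(nf$b), type = "open")
    a <- convolve(bp$a, rev(nf$a), type = "open")
  } else {
    b <- bp$b; a <- bp$a
  }
  out <- rec$data
  n <- ncol(out)
  if (n > 200000L) {
    # spectral zero-phase application of the same transfer function
    # (|H(f)|^2, i.e. forward-backward), much faster on hours-long signals
    N <- stats::nextn(n + 4096L, c(2L, 3L, 5L))   # smooth FFT length
    H2 <- zero_phase_response(b, a, N)
    for (i in seq_len(nrow(out)))
      out[i, ] <- fft_zero_phase(out[i, ], H2, n)
  } else {
    flt <- signal::Arma(b = b, a = a)
    for (i in seq_len(nrow(out)))
      out[i, ] <- signal::filtfilt(flt, out[i, ])
  }
  eeg_recording(out, rec$fs, rec$channel_ids, rec$pma_weeks, rec$meta,
                validate = FALSE)
}

#' Discard channels with excessive missing signal
#'
#' Missingness is marked as non-finite samples (electrode drop-off).
#' Channels whose non-finite fraction strictly exceeds `missing_frac` are
#' removed; remaining gaps on surviving channels are linearly interpolated.
#'
#' @param rec an `eeg_recording`.
#' @param missing_frac maximum tolerated missing fraction (default 0.20).
#' @return an `eeg_recording` with only surviving channels, all finite.
#' @export
drop_bad_channels <- function(rec, missing_frac = 0.20) {
  frac <- rowMeans(!is.finite(rec$data))
  keep <- frac <= missing_frac
  if (!any(keep))
    stop("data-quality error: all channels exceed the missing-signal limit")
  if (any(!keep))
    message("discarding channel(s) with >", missing_frac * 100, "% missing: ",
            paste(rec$channel_ids[!keep], collapse = ", "))
  X <- rec$data[keep, , drop = FALSE]
  n <- ncol(X)
  for (i in seq_len(nrow(X))) {
    bad <- !is.finite(X[i, ])
    if (any(bad)) {
      good <- which(!bad)
      X[i, bad] <- stats::approx(good, X[i, good], xout = which(bad),
                                 rule = 2)$y
    }
  }
  eeg_recording(X, rec$fs, rec$channel_ids[keep], rec$pma_weeks, rec$meta)
}

#' Downsample a recording by an integer factor
#'
#' Intended for recordings already band-limited by [bandpass_notch()] (a
#' 1-40 Hz signal at 250 Hz safely decimates by 3 to 83.33 Hz). A Butterworth
#' anti-alias guard is applied anyway for robustness to caller misuse.
#'
#' @param rec an `eeg_recording`.
#' @param factor integer decimation factor (default 3).
#' @return decimated `eeg_recording` at `fs / factor`.
#' @export
downsample <- function(rec, factor = 3) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("decimation factor must be >= 1")
  if (factor == 1L) return(rec)
  # zero-phase anti-alias guard: linear-phase FIR (Hamming), centered;
  # evaluated only at the retained samples (polyphase-style)
  guard <- as.numeric(signal::fir1(30, 0.9 / factor))
  L <- length(guard); half <- (L - 1L) %/% 2L
  n <- ncol(rec$data)
  idx <- seq(1L, n, by = factor)
  out <- matrix(0, nrow(rec$data), length(idx))
  for (i in seq_len(nrow(rec$data))) {
    xp <- c(numeric(half), rec$data[i, ], numeric(half))
    acc <- numeric(length(idx))
    for (k in seq_len(L)) acc <- acc + guard[k] * xp[idx + (k - 1L)]
    out[i, ] <- acc
  }
  eeg_recording(out, rec$fs / factor, rec$channel_ids, rec$pma_weeks,
                rec$meta, validate = FALSE)
}
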