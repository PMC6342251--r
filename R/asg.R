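# Adaptive segmentation (ASG): locate nonstationary boundaries per channel
# from a weighted amplitude/frequency difference signal computed between two
# contiguous sliding windows.
#
#   ADIF = sum |x(i)|             (amplitude measure)
#   FDIF = sum |x(i) - x(i-1)|    (frequency measure, total variation)
#   G    = |ADIF1 - ADIF2| + kF * |FDIF1 - FDIF2|
#
# Boundaries are the peaks of G(t) above MINPEAKHEIGHT, at least
# MINPEAKDISTANCE apart. Signals are expected in microvolts: the tuned
# MINPEAKHEIGHT is amplitude-dimensional through ADIF.

#' Amplitude difference measure of one window
#' @param window numeric vector.
#' @return sum of absolute amplitudes.
#' @export
adif <- function(window) {
  if (!length(window)) stop("adif needs a non-empty window")
  sum(abs(window))
}

#' Frequency difference measure (total variation) of one window
#'
#' `x(0)` - the sample preceding the window - may be supplied via `prev`;
#' at the recording edge the first in-window sample is used (zero first
#' difference).
#'
#' @param window numeric vector, length >= 2.
#' @param prev sample preceding the window (default: first window sample).
#' @return sum of absolute first differences.
#' @export
fdif <- function(window, prev = window[1]) {
  if (length(window) < 2L) stop("fdif needs a window of length >= 2")
  sum(abs(diff(c(prev, window))))
}

#' Weighted amplitude/frequency difference signal G(t)
#'
#' For each shift position t, two contiguous windows `[t-win, t)` and
#' `[t, t+win)` of `win_s` seconds are compared:
#' `G(t) = |ADIF1-ADIF2| + kf * |FDIF1-FDIF2|`. G is timestamped at the
#' window junction (the candidate change point).
#'
#' @param channel numeric vector (one EEG channel, microvolts, downsampled).
#' @param fs sampling rate, Hz.
#' @param win_s window length, seconds (tuned default 0.7).
#' @param shift_samples shift step, samples (tuned default 9).
#' @param kf integer weight of the frequency measure (tuned default 10).
#' @return list with `g` (values) and `pos` (1-based sample index of the
#'   junction: the first sample of the second window).
#' @export
g_signal <- function(channel, fs, win_s = 0.7, shift_samples = 9L, kf = 10) {
  win <- as.integer(round(win_s * fs))
  n <- length(channel)
  if (n < 2L * win) stop("channel shorter than two analysis windows")
  csA <- cumsum(c(0, abs(channel)))
  d <- abs(diff(channel))           # d[i] = |x(i+1) - x(i)|
  csF <- cumsum(c(0, d))
  # window starting at sample s (length win): ADIF = csA[s+win] - csA[s];
  # FDIF uses the preceding sample as x(0): sum d[(s-1):(s+win-2)]
  pos <- seq(win + 1L, n - win + 1L, by = as.integer(shift_samples))
  s1 <- pos - win                    # first window start
  s2 <- pos                          # second window start
  A1 <- csA[s1 + win] - csA[s1]
  A2 <- csA[s2 + win] - csA[s2]
  fd <- function(s) {
    lo <- pmax(s - 1L, 1L)
    csF[s + win - 1L] - csF[lo]      # d indices lo..s+win-2
  }
  G <- abs(A1 - A2) + kf * abs(fd(s1) - fd(s2))
  list(g = G, pos = pos)
}

#' Detect segment boundaries from G(t)
#'
#' Local maxima of G above `minpeakheight`, thinned greedily (highest peak
#' first) so surviving peaks are at least `minpeakdistance_samples` apart on
#' the G grid. Peak positions are mapped back to signal sample offsets and
#' 0 / `n_samples` appended as outer boundaries.
#'
#' @param g result of [g_signal()].
#' @param n_samples channel length in samples.
#' @param minpeakheight minimum peak height (tuned default 100, uV-scale).
#' @param minpeakdistance_samples minimum peak separation on the G grid
#'   (tuned default 25).
#' @return a `segment_list`: list with `boundaries` (0-based sample offsets,
#'   first 0, last `n_samples`) and `segments` (two-column matrix of
#'   half-open `[start, end)` offsets).
#' @export
detect_boundaries <- function(g, n_samples, minpeakheight = 100,
                              minpeakdistance_samples = 25L) {
  G <- g$g
  m <- length(G)
  cand <- integer(0)
  if (m >= 3L) {
    inner <- 2L:(m - 1L)
    is_peak <- G[inner] > G[inner - 1L] & G[inner] >= G[inner + 1L] &
      G[inner] > minpeakheight
    cand <- inner[is_peak]
  }
  keep <- integer(0)
  if (length(cand)) {
    # greedy highest-first with distance suppression via an occupancy grid
    cand <- cand[order(G[cand], decreasing = TRUE)]
    d <- as.integer(minpeakdistance_samples)
    blocked <- logical(m)
    sel <- logical(length(cand))
    for (i in seq_along(cand)) {
      p <- cand[i]
      if (!blocked[p]) {
        sel[i] <- TRUE
        blocked[max(1L, p - d + 1L):min(m, p + d - 1L)] <- TRUE
      }
    }
    keep <- sort(cand[sel])
  }
  b <- sort(unique(c(0L, g$pos[keep] - 1L, as.integer(n_samples))))
  b <- b[b >= 0L & b <= n_samples]
  segment_list(b, n_samples)
}

# Validated segment-list constructor: strictly increasing boundaries tiling
# [0, n_samples).
segment_list <- function(boundaries, n_samples, channel_id = NA_character_) {
  b <- as.integer(boundaries)
  if (b[1] != 0L || b[length(b)] != n_samples || any(diff(b) < 1L))
    stop("invalid segment boundaries")
  structure(list(boundaries = b,
                 segments = cbind(start = b[-length(b)], end = b[-1L]),
                 channel_id = channel_id),
            class = "segment_list")
}

#' Segment one channel
#'
#' Composition of [g_signal()] and [detect_boundaries()]; on realistic
#' preterm EEG the resulting segments are typically 1-5 s long. The
#' `uniform1` / `uniform5` segmenters are the uniform-segmentation ablations
#' (fixed 1 s or 5 s tiles) sharing the same contract.
#'
#' @param channel numeric vector, microvolts.
#' @param fs sampling rate, Hz.
#' @param win_s,shift_samples,kf see [g_signal()].
#' @param minpeakheight,minpeakdistance_samples see [detect_boundaries()].
#' @param segmenter `"adaptive"` (default), `"uniform1"` or `"uniform5"`.
#' @return a `segment_list`.
#' @export
segment_channel <- function(channel, fs, win_s = 0.7, shift_samples = 9L,
                            kf = 10, minpeakheight = 100,
                            minpeakdistance_samples = 25L,
                            segmenter = c("adaptive", "uniform1", "uniform5")) {
  segmenter <- match.arg(segmenter)
  n <- length(channel)
  if (segmenter != "adaptive") {
    tile <- as.integer(round(fs * if (segmenter == "uniform1") 1 else 5))
    b <- seq(0L, n, by = tile)
    if (b[length(b)] != n) b <- c(b, n)
    if (length(b) < 2L) b <- c(0L, n)
    return(segment_list(b, n))
  }
  g <- g_signal(channel, fs, win_s, shift_samples, kf)
  detect_boundaries(g, n, minpeakheight, minpeakdistance_samples)
}
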