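# Internal numerical helpers shared across the pipeline.

#' Centered moving average with reflected edges
#'
#' Computes a centered moving-average of `x` with window `n`, padding both
#' ends by reflection so that the filter output has the same length as the
#' input and does not collapse toward zero at the recording edges.
#'
#' @param x numeric vector.
#' @param n window length in samples; shrunk (with a warning) when it exceeds
#'   `length(x)`.
#' @return numeric vector, `length(x)`.
#' @keywords internal
ma_reflect <- function(x, n) {
  len <- length(x)
  if (len == 0L) return(x)
  n <- as.integer(n)
  if (n < 1L) stop("moving-average window must be >= 1 sample")
  if (n > len) {
    warning(sprintf("moving-average window (%d) longer than signal (%d); shrunk", n, len))
    n <- len
  }
  if (n == 1L) return(x)
  left <- (n - 1L) %/% 2L
  right <- n - 1L - left
  # reflect without repeating the edge sample (mirror about the end points)
  pre <- if (left > 0L) x[pmin(len, left + 1L):2L] else numeric(0)
  post <- if (right > 0L) x[(len - 1L):pmax(1L, len - right)] else numeric(0)
  xp <- c(pre, x, post)
  cs <- cumsum(xp)
  (cs[(n):length(xp)] - c(0, cs[seq_len(length(xp) - n)])) / n
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded internals (e.g.
#' k-means restarts) do not perturb the caller's random stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a reproducible child seed from a parent seed and a stream tag, so
# the simulator's sub-streams (states, waveforms, artifacts) are
# independently reproducible. Kept below 2^31.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 9973) %% 2147483647)
}

#' One-sided periodogram
#'
#' Rectangular-windowed, one-sided periodogram scaled so that
#' `sum(psd) * df` equals the signal's mean square (power), with
#' `df = fs / n`.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @keywords internal
periodogram_psd <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  nh <- n %/% 2L
  psd2 <- (Mod(X)^2) / (n * fs)        # two-sided, power/Hz
  keep <- seq_len(nh + 1L)
  psd <- psd2[keep]
  # fold negative frequencies onto positive ones (except DC and Nyquist)
  if (nh >= 2L) {
    inner <- 2L:(if (n %% 2L == 0L) nh else nh + 1L)
    psd[inner] <- psd[inner] * 2
  }
  list(freq = (keep - 1L) * fs / n, psd = psd)
}

#' Welch power spectral density
#'
#' Hann-windowed, 50%-overlapping segment-averaged periodogram. Used for the
#' maturation band powers where a stable spectral estimate over a 30 s-20 min
#' epoch matters more than resolution.
#' @keywords internal
welch_psd <- function(x, fs, seg_s = 4, overlap = 0.5) {
  nseg <- max(8L, as.integer(round(seg_s * fs)))
  n <- length(x)
  if (n < nseg) nseg <- n
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  wnorm <- sum(w^2)
  nh <- nseg %/% 2L
  acc <- numeric(nh + 1L)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    p2 <- (Mod(X)^2) / (wnorm * fs)
    p <- p2[seq_len(nh + 1L)]
    if (nh >= 2L) {
      inner <- 2L:(if (nseg %% 2L == 0L) nh else nh + 1L)
      p[inner] <- p[inner] * 2
    }
    acc <- acc + p
  }
  list(freq = (seq_len(nh + 1L) - 1L) * fs / nseg, psd = acc / length(starts))
}

# Integrate a PSD over a frequency band [lo, hi) by the rectangle rule.
band_power <- function(freq, psd, lo, hi) {
  df <- if (length(freq) > 1L) freq[2] - freq[1] else 1
  sel <- freq >= lo & freq < hi
  sum(psd[sel]) * df
}

# Trapezium integration of y over x (x need not be sorted; sorted internally).
trapz <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Runs of TRUE in a logical vector -> matrix of (start, end) indices
# (1-based, inclusive).
true_runs <- function(ind) {
  r <- rle(as.logical(ind))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Squared magnitude response |H|^2 of the digital filter (b, a) on the
# N-point DFT grid: the transfer function of one forward plus one backward
# pass (zero phase).
zero_phase_response <- function(b, a, N) {
  z <- exp(-2i * pi * (seq_len(N) - 1L) / N)
  horner <- function(p) {
    acc <- complex(length.out = N, real = p[1])
    for (k in seq_along(p)[-1]) acc <- acc * z + p[k]
    acc
  }
  H <- horner(b) / horner(a)
  Re(H * Conj(H))
}

# Apply a real, zero-phase spectral response to x (zero-padded to the
# response length to avoid circular wrap of the filter tail).
fft_zero_phase <- function(x, H2, n_out = length(x)) {
  N <- length(H2)
  X <- stats::fft(c(x, numeric(N - length(x))))
  Re(stats::fft(X * H2, inverse = TRUE))[seq_len(n_out)] / N
}
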