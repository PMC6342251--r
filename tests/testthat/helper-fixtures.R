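# Shared fixture builders and independent oracles.

# Sine-wave recording
sine_recording <- function(freqs, fs = 250, dur_s = 30, amp = 1) {
  t <- seq_len(fs * dur_s) / fs
  X <- t(vapply(freqs, function(f) amp * sin(2 * pi * f * t), numeric(length(t))))
  eeg_recording(X, fs, paste0("S", seq_along(freqs)))
}

# Burst/IBI square-envelope channel: alternating quiet and burst spans with
# band-limited noise content. Returns the signal and the true burst mask.
square_envelope_channel <- function(fs = 250, n_cycles = 20, burst_s = 3,
                                    quiet_s = 3, burst_amp = 60,
                                    quiet_amp = 8, seed = 7, lo = 1, hi = 15) {
  set.seed(seed)
  nb <- round(burst_s * fs); nq <- round(quiet_s * fs)
  n <- n_cycles * (nb + nq)
  noise <- as.numeric(signal::filter(signal::butter(2, c(lo, hi) / (fs / 2), "pass"),
                                     rnorm(n)))
  noise <- noise / sd(noise)
  env <- rep(rep(c(quiet_amp, burst_amp), times = c(nq, nb)), n_cycles)
  mask <- rep(rep(c(FALSE, TRUE), times = c(nq, nb)), n_cycles)
  list(x = env * noise, mask = mask, fs = fs)
}

# Random small hypnogram over [0, span) with up to max_int QS intervals
random_hypnogram <- function(span = 1000, max_int = 5) {
  k <- sample.int(max_int, 1)
  cuts <- sort(runif(2 * k, 0, span))
  starts <- cuts[seq(1, 2 * k, by = 2)]
  ends <- cuts[seq(2, 2 * k, by = 2)]
  ok <- ends - starts > 1e-3
  intervals_to_hyp(starts[ok], ends[ok], span)
}

intervals_to_hyp <- function(starts, ends, span) {
  df <- data.frame(start_s = starts, end_s = ends)
  classqs:::intervals_to_hypnogram(df, 0, span)
}

# Brute-force DF/MF oracle: all pairwise intersections, no shortcuts.
brute_event_metrics <- function(pred, ref, frac = 0.5) {
  vis <- pred_qs <- NULL
  vis <- ref[ref$state == "QS", , drop = FALSE]
  det <- pred[pred$state == "QS", , drop = FALSE]
  match_ij <- function(i, j) {
    inter <- min(vis$end_s[i], det$end_s[j]) - max(vis$start_s[i], det$start_s[j])
    inter > frac * min(vis$end_s[i] - vis$start_s[i], det$end_s[j] - det$start_s[j])
  }
  vh <- rep(FALSE, nrow(vis)); dh <- rep(FALSE, nrow(det))
  if (nrow(vis) && nrow(det)) {
    for (i in seq_len(nrow(vis))) for (j in seq_len(nrow(det))) {
      if (match_ij(i, j)) { vh[i] <- TRUE; dh[j] <- TRUE }
    }
  }
  list(df = if (nrow(vis)) mean(vh) else NA_real_,
       mf = if (nrow(det)) mean(!dh) else NA_real_)
}

# Hand-assembled oracle for the reconstruction matrix: every symbol of
# R = M (V'M o A)^+ V' built step by step with an SVD pseudo-inverse.
oracle_reconstruction <- function(V, A, M) {
  P <- (t(V) %*% M) * A
  sv <- svd(P)
  tol <- max(dim(P)) * max(sv$d) * .Machine$double.eps
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  pinv <- sv$v %*% diag(dinv, length(dinv)) %*% t(sv$u)
  M %*% pinv %*% t(V)
}

# Scalar-loop NLEO oracle
nleo_loop <- function(x) {
  n <- length(x)
  psi <- numeric(n)
  for (i in seq_len(n)) {
    if (i >= 4) psi[i] <- x[i] * x[i - 3] - x[i - 1] * x[i - 2]
  }
  psi
}

# Windowed RMS over non-overlapping win_s windows
windowed_rms <- function(x, fs, win_s = 1) {
  w <- round(win_s * fs)
  nb <- floor(length(x) / w)
  vapply(seq_len(nb), function(b) sqrt(mean(x[((b - 1) * w + 1):(b * w)]^2)), 0)
}
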