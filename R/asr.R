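# Artifact Subspace Reconstruction (ASR).
#
# Calibration: robust PCA of a clean ~1 min epoch via the geometric-median
# covariance; per-component RMS thresholds t_c = mu_c + asr_thresh * sigma_c
# from a Gaussian fitted to 0.5 s / 66%-overlap segment RMS values.
# Cleaning: sliding-window PCA; window components whose variance exceeds the
# projected calibration thresholds span the artifact subspace and are
# removed by a per-window reconstruction matrix
#   R = M (V'M o A)^+ V'    (o elementwise, ^+ pseudo-inverse).

#' Geometric-median covariance
#'
#' Robust covariance of a channels-by-samples matrix: the matrix minimizing
#' the summed Frobenius distances to the per-sample outer products
#' \eqn{x_i x_i^\top}, found by Weiszfeld iteration. Unlike the mean
#' covariance it is barely skewed by sparse high-power artifacts left in the
#' calibration data.
#'
#' @param X numeric matrix, channels x samples, zero-mean.
#' @param tol relative convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 500); on non-convergence a warning
#'   is issued and the coordinate-wise median of the outer products is
#'   returned instead.
#' @return symmetric positive semi-definite channels x channels matrix.
#' @export
geometric_median_covariance <- function(X, tol = 1e-6, max_iter = 500L) {
  if (!all(is.finite(X))) stop("geometric-median covariance needs finite data")
  c_ <- nrow(X); n <- ncol(X)
  if (n < 1L) stop("need at least one sample")
  # per-sample outer products, one row each (row-major vec of x_i x_i^T)
  P <- t(apply(X, 2L, function(x) as.vector(tcrossprod(x))))
  Y <- colMeans(P)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- sqrt(rowSums(sweep(P, 2L, Y)^2))
    d[d < 1e-12] <- 1e-12
    w <- 1 / d
    Ynew <- colSums(P * w) / sum(w)
    if (sqrt(sum((Ynew - Y)^2)) <= tol * max(sqrt(sum(Y^2)), 1e-300)) {
      Y <- Ynew; converged <- TRUE; break
    }
    Y <- Ynew
  }
  if (!converged) {
    warning("geometric-median covariance did not converge; falling back to coordinate-wise median")
    Y <- apply(P, 2L, stats::median)
  }
  Y <- matrix(Y, c_, c_)
  (Y + t(Y)) / 2
}

# RMS of sliding segments (seg samples, fractional overlap) of a vector.
segment_rms <- function(x, seg, overlap_frac) {
  step <- max(1L, as.integer(round(seg * (1 - overlap_frac))))
  starts <- seq(1L, length(x) - seg + 1L, by = step)
  cs <- cumsum(c(0, x^2))
  sqrt((cs[starts + seg] - cs[starts]) / seg)
}

#' Calibrate an ASR model from a clean epoch
#'
#' @param calib an `eeg_recording` epoch (~60 s) of artifact-free, zero-mean
#'   (band-passed) EEG.
#' @param asr_thresh threshold weight separating artifact and artifact-free
#'   subspaces (tuned default 10).
#' @param seg_dur_s RMS segment duration, seconds (default 0.5, the typical
#'   time length of EEG discontinuities).
#' @param overlap_frac RMS segment overlap (default 0.66).
#' @return an `asr_model`: diagonal threshold matrix `T` (RMS units, uV),
#'   mixing matrix `M` with `Y = M M'`, calibration eigenvectors `V_Y`, and
#'   the calibration parameters.
#' @export
asr_calibrate <- function(calib, asr_thresh = 10, seg_dur_s = 0.5,
                          overlap_frac = 0.66) {
  X <- calib$data
  seg <- as.integer(round(seg_dur_s * calib$fs))
  if (ncol(X) < 10L * seg)
    stop("calibration epoch too short (need >= 10 RMS segments)")
  Y <- geometric_median_covariance(X)
  eg <- eigen(Y, symmetric = TRUE)
  if (min(eg$values) < 1e-10 * max(eg$values)) {
    null_dirs <- which(eg$values < 1e-10 * max(eg$values))
    chans <- unique(vapply(null_dirs, function(j)
      calib$channel_ids[which.max(abs(eg$vectors[, j]))], ""))
    stop("rank-deficient calibration covariance; degenerate channel(s): ",
         paste(chans, collapse = ", "))
  }
  V_Y <- eg$vectors
  comps <- t(V_Y) %*% X                     # principal components
  t_c <- apply(comps, 1L, function(pc) {
    r <- segment_rms(pc, seg, overlap_frac)
    # Gaussian fitted on the central mass to stay robust to residual
    # artifact extremities in the RMS distribution
    q <- stats::quantile(r, c(0.01, 0.95), names = FALSE)
    core <- r[r >= q[1] & r <= q[2]]
    mu <- mean(core); sd_ <- stats::sd(core)
    if (!is.finite(sd_)) sd_ <- 0
    mu + asr_thresh * sd_
  })
  M <- V_Y %*% diag(sqrt(eg$values), nrow(X)) %*% t(V_Y)   # symmetric root
  structure(list(T = diag(t_c, nrow(X)), M = M, V_Y = V_Y, Y = Y,
                 asr_thresh = asr_thresh, seg_dur_s = seg_dur_s,
                 overlap_frac = overlap_frac, channel_ids = calib$channel_ids,
                 fs = calib$fs),
            class = "asr_model")
}

#' @export
print.asr_model <- function(x, ...) {
  cat(sprintf("<asr_model> %d channels, asr_thresh = %g, thresholds (uV RMS): %s\n",
              nrow(x$T), x$asr_thresh,
              paste(signif(diag(x$T), 3), collapse = ", ")))
  invisible(x)
}

#' Decompose one EEG window against an ASR model
#'
#' PCA of the window, projection of the calibration thresholds into the
#' window's component space (`T_proj = T V_Y' V`), and the binary keep /
#' reject matrix `A`: component j is kept iff its eigenvalue (variance) lies
#' below the column-wise sum of squared projected thresholds.
#'
#' @param S numeric matrix, channels x samples (zero-mean window).
#' @param model an `asr_model` over the same channel set.
#' @return list with `V`, `lambda`, `T_proj`, `A` (rows all-ones or
#'   all-zeros per component) and `keep` (logical per component).
#' @export
window_decomposition <- function(S, model) {
  c_ <- nrow(S)
  if (c_ != nrow(model$T)) stop("window channel count does not match ASR model")
  Sigma <- tcrossprod(S) / max(1L, ncol(S) - 1L)
  eg <- eigen(Sigma, symmetric = TRUE)
  V <- eg$vectors
  lambda <- pmax(eg$values, 0)
  T_proj <- model$T %*% t(model$V_Y) %*% V
  thr2 <- colSums(T_proj^2)
  keep <- lambda < thr2
  # numerical degeneracy (NaN comparison) -> reject and log
  bad <- !is.finite(keep)
  if (any(bad)) {
    keep[bad] <- FALSE
    message("ASR: rejecting ", sum(bad), " numerically degenerate component(s)")
  }
  A <- matrix(as.numeric(keep), c_, c_)   # row j constant = keep[j]
  list(V = V, lambda = lambda, T_proj = T_proj, A = A, keep = keep)
}

#' Reconstruction matrix for one window
#'
#' `R = M (V'M o A)^+ V'` with `o` elementwise multiplication and `^+` the
#' Moore-Penrose pseudo-inverse. With all components kept, `R` is the
#' identity; rejected components contribute nothing to the reconstruction.
#'
#' @param dec a [window_decomposition()] result.
#' @param model the `asr_model`.
#' @return channels x channels reconstruction matrix.
#' @export
reconstruction_matrix <- function(dec, model) {
  VtM <- crossprod(dec$V, model$M)
  model$M %*% MASS::ginv(VtM * dec$A) %*% t(dec$V)
}

#' Clean a recording by sliding-window subspace reconstruction
#'
#' For each output sample, the reconstruction matrix of the window centered
#' on it is applied to the sample's channel vector; windows rejecting no
#' component have the identity reconstruction, so only rejection regions
#' need explicit work. At the recording edges the window shrinks to the
#' available data. With `stride_samples > 1` a coarse pass locates the
#' windows that reject components, and only their neighborhoods are
#' re-cleaned at `refine_stride` resolution - far cheaper than the
#' sample-by-sample definition with near-identical output (`stride_samples
#' = 1` recomputes everywhere and ignores `refine_stride`).
#'
#' @param rec zero-mean `eeg_recording` over the model's channels.
#' @param model an `asr_model`.
#' @param window_s sliding-window length, seconds (default 0.5).
#' @param stride_samples coarse detection stride (default 1).
#' @param refine_stride reconstruction-matrix reuse inside rejection
#'   regions (default 2 samples).
#' @return cleaned `eeg_recording`; attribute `n_rejected_windows` counts
#'   coarse windows where at least one component was removed.
#' @export
asr_clean <- function(rec, model, window_s = 0.5, stride_samples = 1L,
                      refine_stride = 2L) {
  if (!identical(rec$channel_ids, model$channel_ids))
    stop("recording channels do not match ASR model channels")
  X <- rec$data
  n <- ncol(X)
  half <- max(1L, as.integer(round(window_s * rec$fs / 2)))
  stride <- max(1L, as.integer(stride_samples))
  out <- X
  decompose <- function(t0) {
    lo <- max(1L, t0 - half); hi <- min(n, t0 + half)
    window_decomposition(X[, lo:hi, drop = FALSE], model)
  }
  if (stride == 1L) {
    nrej <- 0L
    for (t0 in seq_len(n)) {
      dec <- decompose(t0)
      if (all(dec$keep)) next
      nrej <- nrej + 1L
      out[, t0] <- reconstruction_matrix(dec, model) %*% X[, t0]
    }
  } else {
    # coarse pass: find windows with rejections
    centers <- seq(1L, n, by = stride)
    hit <- vapply(centers, function(t0) !all(decompose(t0)$keep), logical(1))
    nrej <- sum(hit)
    if (nrej > 0L) {
      # refine around every rejecting coarse window
      mask <- logical(n)
      for (t0 in centers[hit]) {
        lo <- max(1L, t0 - half - stride)
        hi <- min(n, t0 + half + stride)
        mask[lo:hi] <- TRUE
      }
      refine <- max(1L, as.integer(refine_stride))
      runs <- true_runs(mask)
      for (r in seq_len(nrow(runs))) {
        for (t0 in seq(runs[r, "start"], runs[r, "end"], by = refine)) {
          dec <- decompose(t0)
          if (all(dec$keep)) next
          idx <- t0:min(runs[r, "end"], t0 + refine - 1L)
          out[, idx] <- reconstruction_matrix(dec, model) %*%
            X[, idx, drop = FALSE]
        }
      }
    }
  }
  res <- eeg_recording(out, rec$fs, rec$channel_ids, rec$pma_weeks, rec$meta,
                       validate = FALSE)
  attr(res, "n_rejected_windows") <- nrej
  res
}

#' Select a calibration epoch automatically
#'
#' Scores every contiguous `duration_s` epoch by its per-channel windowed
#' RMS (0.5 s windows) z-scored against robust whole-recording statistics
#' (median / MAD per channel). Epochs containing any window beyond
#' `z_cutoff` are treated as artifact-contaminated; among the remaining
#' epochs the one with the *largest* RMS dynamics (summed per-channel RMS
#' spread) is selected, because calibration thresholds
#' `t_c = mu_c + asr_thresh sigma_c` must span the recording's normal
#' burst/interburst amplitude range - an epoch that is merely quiet would
#' under-estimate them and reject genuine EEG discontinuities. When no
#' epoch passes the artifact guard, the epoch with the smallest peak
#' z-score is used instead. An explicit `(start_s, end_s)` overrides the
#' heuristic.
#'
#' @param rec an `eeg_recording`.
#' @param duration_s epoch length, seconds (default 60).
#' @param start_s,end_s optional manual epoch bounds, seconds.
#' @param z_cutoff artifact guard on the windowed-RMS robust z-score
#'   (default 15: movement artifacts sit an order of magnitude above the
#'   background, physiological bursts within ~10 robust SDs).
#' @return an `eeg_recording` epoch; attribute `calibration_start_s` records
#'   its position.
#' @export
select_calibration <- function(rec, duration_s = 60, start_s = NULL,
                               end_s = NULL, z_cutoff = 15) {
  if (duration_s(rec) < duration_s)
    stop("recording shorter than the requested calibration duration")
  if (!is.null(start_s)) {
    epoch <- slice_recording(rec, start_s, end_s %||% (start_s + duration_s))
    attr(epoch, "calibration_start_s") <- start_s
    return(epoch)
  }
  seg <- max(2L, as.integer(round(0.5 * rec$fs)))
  rms <- t(apply(rec$data, 1L, function(x) segment_rms(x, seg, 0)))
  z <- t(apply(rms, 1L, function(r) {
    s <- stats::mad(r); if (!is.finite(s) || s == 0) s <- 1
    (r - stats::median(r)) / s
  }))
  worst <- apply(z, 2L, max)                     # worst channel per window
  span <- as.integer(ceiling(duration_s / 0.5))  # windows per epoch
  nw <- length(worst)
  if (span >= nw) span <- nw
  starts <- seq_len(nw - span + 1L)
  peak <- vapply(starts, function(i) max(worst[i:(i + span - 1L)]), 0)
  dyn <- vapply(starts, function(i) {
    idx <- i:(i + span - 1L)
    sum(apply(rms[, idx, drop = FALSE], 1L, stats::sd))
  }, 0)
  eligible <- peak <= z_cutoff
  best <- if (any(eligible)) starts[eligible][which.max(dyn[eligible])]
          else starts[which.min(peak)]
  t0 <- (best - 1L) * 0.5
  epoch <- slice_recording(rec, t0, t0 + duration_s)
  attr(epoch, "calibration_start_s") <- t0
  epoch
}
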