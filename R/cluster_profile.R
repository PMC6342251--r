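# Segment features, k-means clustering with variance relabeling, and
# per-channel cluster-time profiles.
#
# Each adaptive segment is summarized by nine time- and frequency-domain
# features; all segments from all channels are clustered together; clusters
# are relabeled by increasing mean variance so the integer label itself
# tracks EEG "activity level". Replacing every sample by its segment's label
# yields the cluster-time profile whose fluctuation magnitude tracks
# discontinuity - the signature quiet sleep detection keys on.

FEATURE_NAMES <- c("sd", "range", "d1max", "d2max", "mean_freq",
                   "p_delta", "p_theta", "p_alpha", "p_beta")

#' Extract the nine segment features
#'
#' Amplitude standard deviation, amplitude range, maximum absolute first and
#' second differences, periodogram mean frequency, and square roots of the
#' band powers in delta (1-3 Hz), theta (3-8 Hz), alpha (8-12 Hz) and beta
#' (12-30 Hz). Spectral quantities come from the rectangular one-sided
#' periodogram of the segment (no zero-padding).
#'
#' @param segment numeric vector (>= 4 samples), microvolts.
#' @param fs sampling rate, Hz.
#' @return named numeric vector of the nine features.
#' @export
extract_features <- function(segment, fs) {
  n <- length(segment)
  if (n < 4L) stop("segments shorter than 4 samples must be merged before feature extraction")
  d1 <- diff(segment)
  d2 <- diff(d1)
  pg <- periodogram_psd(segment - mean(segment), fs)
  pw <- pg$psd
  pw_tot <- sum(pw[pg$freq > 0])
  mean_freq <- if (pw_tot > 0) sum(pg$freq * pw) / sum(pw) else 0
  c(sd = stats::sd(segment),
    range = max(segment) - min(segment),
    d1max = max(abs(d1)),
    d2max = max(abs(d2)),
    mean_freq = mean_freq,
    p_delta = sqrt(band_power(pg$freq, pw, 1, 3)),
    p_theta = sqrt(band_power(pg$freq, pw, 3, 8)),
    p_alpha = sqrt(band_power(pg$freq, pw, 8, 12)),
    p_beta = sqrt(band_power(pg$freq, pw, 12, 30)))
}

# Merge segments shorter than min_len samples into their predecessor (the
# first segment merges forward), so every segment supports a second
# difference.
merge_short_segments <- function(seg, min_len = 4L) {
  b <- seg$boundaries
  n <- b[length(b)]
  repeat {
    len <- diff(b)
    short <- which(len < min_len)
    if (!length(short)) break
    i <- short[1]
    # drop the boundary between segment i and its predecessor (or successor
    # when i is the first segment)
    drop <- if (i == 1L) 2L else i
    if (length(b) <= 2L) break
    b <- b[-drop]
  }
  segment_list(b, n, seg$channel_id)
}

# Feature matrix (segments x 9) for one channel's segment list.
channel_feature_matrix <- function(channel, seg, fs) {
  t(apply(seg$segments, 1L, function(s)
    extract_features(channel[(s[1] + 1L):s[2]], fs)))
}

#' Cluster segment features with k-means
#'
#' Features are z-scored (the microvolt-scale features would otherwise
#' dominate the Euclidean distance), then clustered with `k`-means, best of
#' `reps` random restarts by within-cluster sum of squares. Deterministic
#' under a fixed `seed`.
#'
#' @param features numeric matrix, segments x features (all channels pooled).
#' @param k number of clusters (tuned default 12).
#' @param reps number of k-means restarts (default 20).
#' @param seed RNG seed for the restarts.
#' @return integer vector of raw cluster labels (1..k); attribute `k` holds
#'   the effective cluster count (reduced with a warning when there are
#'   fewer distinct segments than `k`).
#' @export
cluster_segments <- function(features, k = 12L, reps = 20L, seed = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  ndistinct <- nrow(unique(features))
  if (ndistinct < k) {
    warning(sprintf("only %d distinct segments; reducing k from %d", ndistinct, k))
    k <- max(1L, ndistinct)
  }
  mu <- colMeans(features)
  sdv <- apply(features, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  Z <- sweep(sweep(features, 2L, mu), 2L, sdv, "/")
  if (k == 1L) {
    lab <- rep(1L, n)
  } else {
    km <- with_seed(seed, stats::kmeans(Z, centers = k, nstart = reps,
                                        iter.max = 100L))
    lab <- km$cluster
  }
  attr(lab, "k") <- k
  lab
}

#' Relabel clusters by increasing mean variance
#'
#' Cluster label 1 becomes the lowest mean segment variance (`sd^2`), label
#' k the highest; ties broken by cluster size (larger first) then original
#' index.
#'
#' @param labels raw cluster labels.
#' @param features the feature matrix used for clustering (needs an `sd`
#'   column).
#' @return integer labels with the variance ordering; attribute `k` kept.
#' @export
relabel_by_variance <- function(labels, features) {
  k <- attr(labels, "k") %||% max(labels)
  mean_var <- vapply(seq_len(k), function(c_)
    mean(features[labels == c_, "sd"]^2), 0)
  size <- tabulate(labels, k)
  ord <- order(mean_var, -size, seq_len(k))   # increasing variance
  newlab <- integer(k)
  newlab[ord] <- seq_len(k)
  out <- newlab[labels]
  attr(out, "k") <- k
  out
}

#' Build per-channel cluster-time profiles
#'
#' Each sample of each channel is replaced by the cluster label of its
#' enclosing segment.
#'
#' @param seg_lists list of `segment_list`, one per channel.
#' @param labels integer labels for all segments, channel-major (channel 1's
#'   segments first).
#' @param n_samples samples per channel.
#' @return a `cluster_profile`: list with `labels` (channels x samples
#'   integer matrix) and `k`.
#' @export
build_profiles <- function(seg_lists, labels, n_samples) {
  k <- attr(labels, "k") %||% max(labels)
  nch <- length(seg_lists)
  out <- matrix(0L, nch, n_samples)
  off <- 0L
  for (ch in seq_len(nch)) {
    seg <- seg_lists[[ch]]$segments
    lens <- seg[, "end"] - seg[, "start"]
    if (sum(lens) != n_samples) stop("internal error: segments do not tile the channel")
    lab <- labels[off + seq_len(nrow(seg))]
    out[ch, ] <- rep(lab, lens)
    off <- off + nrow(seg)
  }
  if (off != length(labels)) stop("internal error: label/segment count mismatch")
  structure(list(labels = out, k = k), class = "cluster_profile")
}

#' Segment-variance-only profiles (SD ablation)
#'
#' The clustering-free variant: per-segment standard deviations are pooled
#' over channels and quantile-binned into `k` ordered levels, which play the
#' role of variance-ordered cluster labels directly.
#'
#' @param seg_lists list of `segment_list`, one per channel.
#' @param sds numeric vector of per-segment standard deviations,
#'   channel-major.
#' @param n_samples samples per channel.
#' @param k number of levels (default 12).
#' @return a `cluster_profile`.
#' @export
sd_profiles <- function(seg_lists, sds, n_samples, k = 12L) {
  qs <- stats::quantile(sds, probs = seq_len(k - 1L) / k, names = FALSE)
  lab <- findInterval(sds, unique(qs)) + 1L
  attr(lab, "k") <- max(lab)
  build_profiles(seg_lists, lab, n_samples)
}
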