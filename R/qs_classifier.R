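# QS classification: average cluster-time profile -> de-trend -> square ->
# smooth envelope -> mean threshold -> 2 h stitching -> 3-minute rule.

#' Average the cluster-time profile across channels
#' @param profile a `cluster_profile`.
#' @return numeric vector (one value per sample).
#' @export
average_profile <- function(profile) {
  if (!nrow(profile$labels)) stop("profile has no channels")
  colMeans(profile$labels)
}

#' De-trend and square an average profile
#'
#' Subtracts the running mean (centered moving average of `avg_win_length`
#' samples, reflected edges) to remove slow underlying transients, then
#' squares the result to accentuate fluctuation-rich (discontinuous)
#' regions.
#'
#' @param avg average cluster-time profile.
#' @param avg_win_length moving-average window, samples (tuned default 500).
#' @return non-negative numeric vector.
#' @export
detrend_square <- function(avg, avg_win_length = 500L) {
  (avg - ma_reflect(avg, min(avg_win_length, length(avg))))^2
}

#' Smooth the squared profile into an envelope
#'
#' Long centered moving average (reflected edges) of the squared de-trended
#' profile; 35,000 samples is about 7 minutes at 83.33 Hz, the time scale of
#' sleep-state persistence.
#'
#' @param y non-negative vector from [detrend_square()].
#' @param fs sampling rate of the profile, Hz.
#' @param smooth_win_length moving-average window, samples (tuned default
#'   35,000); shrunk with a warning when the input is shorter.
#' @return an `envelope_trace`: list with `values`, `fs`, `block_edges`.
#' @export
smooth_envelope <- function(y, fs, smooth_win_length = 35000L) {
  structure(list(values = ma_reflect(y, smooth_win_length), fs = fs,
                 block_edges = integer(0)),
            class = "envelope_trace")
}

#' Envelope and threshold over stitched 2-hour blocks
#'
#' Long recordings are split into consecutive 2 h blocks (a final partial
#' block is processed as-is); the de-trended, squared, smoothed envelope is
#' derived per block and the pieces stitched; a single global threshold -
#' the mean of the stitched envelope - yields the binary QS indicator
#' (strictly above threshold).
#'
#' @param profile a `cluster_profile`.
#' @param fs profile sampling rate, Hz.
#' @param avg_win_length,smooth_win_length moving-average windows, samples.
#' @param block_s block length, seconds (default 7200).
#' @return list with `envelope` (an `envelope_trace` carrying `threshold`),
#'   and `indicator` (logical per sample).
#' @export
stitch_and_threshold <- function(profile, fs, avg_win_length = 500L,
                                 smooth_win_length = 35000L, block_s = 7200) {
  avg <- average_profile(profile)
  n <- length(avg)
  block <- max(1L, as.integer(round(block_s * fs)))
  starts <- seq(1L, n, by = block)
  env <- numeric(n)
  for (s in starts) {
    e <- min(n, s + block - 1L)
    y <- detrend_square(avg[s:e], avg_win_length)
    env[s:e] <- ma_reflect(y, min(smooth_win_length, length(y)))
  }
  thr <- mean(env)
  trace <- structure(list(values = env, fs = fs,
                          block_edges = starts[-1L] - 1L,
                          threshold = thr),
                     class = "envelope_trace")
  list(envelope = trace, indicator = env > thr)
}

#' Enforce the minimum QS duration (3-minute rule)
#'
#' Maximal above-threshold runs become candidate QS intervals; detections
#' shorter than `min_duration_s` are removed; the complement is labeled
#' non-QS.
#'
#' @param indicator logical vector (QS candidate per sample).
#' @param fs indicator sampling rate, Hz.
#' @param min_duration_s minimum QS duration, seconds (default 180).
#' @return a `hypnogram` tiling `[0, length(indicator)/fs)`.
#' @export
postprocess_min_duration <- function(indicator, fs, min_duration_s = 180) {
  total_s <- length(indicator) / fs
  runs <- true_runs(indicator)
  if (nrow(runs)) {
    start_s <- (runs[, "start"] - 1L) / fs
    end_s <- runs[, "end"] / fs
    keep <- (end_s - start_s) >= min_duration_s
    qs <- data.frame(start_s = start_s[keep], end_s = end_s[keep])
  } else qs <- data.frame(start_s = numeric(0), end_s = numeric(0))
  intervals_to_hypnogram(qs, 0, total_s)
}

#' Run the full quiet-sleep detection pipeline
#'
#' Pre-processing (band-pass + notch, bad-channel discard), ASR cleaning,
#' downsampling, per-channel adaptive segmentation, feature clustering into
#' cluster-time profiles, and envelope thresholding with the 3-minute rule.
#' Ablation variants: `no_asr` (skip cleaning), `usg1` / `usg5` (uniform 1 s
#' / 5 s segmentation), `sd_only` (variance-rank profiles without
#' clustering).
#'
#' @param rec a raw `eeg_recording` (microvolts).
#' @param config a [default_config()] object.
#' @param variant one of `"full"`, `"no_asr"`, `"usg1"`, `"usg5"`,
#'   `"sd_only"` (overrides `config$variant`).
#' @param calibration optional list `(start_s, end_s)` or an `asr_model` to
#'   reuse; by default a clean epoch is auto-selected.
#' @param keep_diagnostics return intermediate artifacts (envelope, profile,
#'   segments, ASR model).
#' @return list with `hypnogram`, `envelope`, and `diagnostics`.
#' @export
run_class <- function(rec, config = default_config(), variant = NULL,
                      calibration = NULL, keep_diagnostics = TRUE) {
  variant <- variant %||% config$variant
  variant <- match.arg(variant, c("full", "no_asr", "usg1", "usg5", "sd_only"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  filt <- stage("preprocess", {
    r <- drop_bad_channels(rec, config$missing_frac)
    bandpass_notch(r, config$low_hz, config$high_hz, config$notch_hz)
  })
  model <- NULL
  if (variant != "no_asr") {
    clean <- stage("asr", {
      model <- if (inherits(calibration, "asr_model")) calibration else {
        epoch <- if (is.list(calibration))
          select_calibration(filt, config$calibration_s,
                             calibration$start_s, calibration$end_s)
        else select_calibration(filt, config$calibration_s)
        asr_calibrate(epoch, config$asr_thresh, config$asr_seg_dur_s,
                      config$asr_overlap_frac)
      }
      asr_clean(filt, model, config$asr_window_s,
                resolve_stride(config$asr_stride, filt$fs))
    })
  } else clean <- filt
  ds <- stage("downsample", downsample(clean, config$ds_factor))
  segmenter <- switch(variant, usg1 = "uniform1", usg5 = "uniform5", "adaptive")
  seg_lists <- stage("asg", lapply(seq_len(nrow(ds$data)), function(ch) {
    s <- segment_channel(ds$data[ch, ], ds$fs, config$win_s,
                         config$shift_samples, config$kf, config$minpeakheight,
                         config$minpeakdistance_samples, segmenter)
    s$channel_id <- ds$channel_ids[ch]
    merge_short_segments(s)
  }))
  profile <- stage("cluster_profile", {
    feats <- do.call(rbind, lapply(seq_along(seg_lists), function(ch)
      channel_feature_matrix(ds$data[ch, ], seg_lists[[ch]], ds$fs)))
    if (variant == "sd_only") {
      sd_profiles(seg_lists, feats[, "sd"], ncol(ds$data), config$k)
    } else {
      lab <- cluster_segments(feats, config$k, config$kmeans_reps, config$seed)
      lab <- relabel_by_variance(lab, feats)
      build_profiles(seg_lists, lab, ncol(ds$data))
    }
  })
  cls <- stage("qs_classifier",
               stitch_and_threshold(profile, ds$fs, config$avg_win_length,
                                    config$smooth_win_length, config$block_s))
  hyp <- postprocess_min_duration(cls$indicator, ds$fs, config$min_duration_s)
  diagnostics <- if (keep_diagnostics)
    list(variant = variant, fs_ds = ds$fs, profile = profile,
         segments = seg_lists, asr_model = model,
         indicator = cls$indicator, config = config)
  else list(variant = variant, fs_ds = ds$fs)
  list(hypnogram = hyp, envelope = cls$envelope, diagnostics = diagnostics)
}
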