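# Pipeline configuration: the tuned parameter set plus pre-processing and
# variant flags.

#' Default pipeline configuration
#'
#' The tuned parameter values selected by perturbation analysis on the
#' training recordings: `asr_thresh` 10, ASG windows of 0.7 s shifted by 9
#' samples with frequency weight `kf` 10, peak thresholds 100 (height) and
#' 25 samples (distance), 12 clusters, de-trending moving average of 500
#' samples and smoothing moving average of 35,000 samples (about 7 min at
#' 83.33 Hz).
#'
#' @param ... named overrides of any default.
#' @return object of class `class_config` (a named list).
#' @export
default_config <- function(...) {
  cfg <- list(
    # pre-processing
    low_hz = 1, high_hz = 40, notch_hz = 50,
    missing_frac = 0.20, ds_factor = 3L,
    # ASR
    asr_thresh = 10, asr_seg_dur_s = 0.5, asr_overlap_frac = 0.66,
    asr_window_s = 0.5, asr_stride = "fs/4", calibration_s = 60,
    # ASG
    win_s = 0.7, shift_samples = 9L, kf = 10,
    minpeakheight = 100, minpeakdistance_samples = 25L,
    # clustering
    k = 12L, kmeans_reps = 20L,
    # QS classification
    avg_win_length = 500L, smooth_win_length = 35000L,
    block_s = 7200, min_duration_s = 180,
    # orchestration
    variant = "full", seed = 42L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "class_config")
}

#' @export
print.class_config <- function(x, ...) {
  cat("<class_config>\n")
  for (nm in names(x)) cat(sprintf("  %s = %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read / write a configuration as YAML
#' @param cfg a `class_config`.
#' @param path YAML file path.
#' @return `read_config` returns a `class_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

# Resolve the ASR stride spec ("fs/4", 1, ...) against a sampling rate.
resolve_stride <- function(stride, fs) {
  if (is.character(stride)) {
    if (grepl("^fs/", stride)) return(max(1L, as.integer(round(fs / as.numeric(sub("fs/", "", stride))))))
    if (stride == "fs") return(as.integer(round(fs)))
    return(as.integer(stride))
  }
  max(1L, as.integer(stride))
}
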