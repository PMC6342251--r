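# Agreement metrics: sample-wise sensitivity/specificity, event-level
# detection and misclassification factors, threshold-sweep ROC with
# trapezium AUC, median ROC across recordings, Cohen's kappa, and
# PMA-grouped summaries.

#' Sample-wise agreement between two hypnograms
#'
#' Both hypnograms are rasterized on a common grid (default 1 Hz, the
#' resolution of visual label files) over their overlapping covered span;
#' QS is the positive class.
#'
#' @param pred,ref predicted and reference `hypnogram`s.
#' @param fs_eval rasterization rate, Hz (default 1).
#' @return list with `confusion` (2x2 counts), `sensitivity`, `specificity`.
#' @export
samplewise_agreement <- function(pred, ref, fs_eval = 1) {
  sp <- hypnogram_span(pred); sr <- hypnogram_span(ref)
  t0 <- max(sp[1], sr[1]); t1 <- min(sp[2], sr[2])
  if (t1 <= t0) stop("hypnograms do not overlap in time")
  p <- rasterize_hypnogram(pred, t0, t1, fs_eval)
  r <- rasterize_hypnogram(ref, t0, t1, fs_eval)
  ok <- !is.na(p) & !is.na(r)
  p <- p[ok]; r <- r[ok]
  tp <- sum(p & r); fn <- sum(!p & r); fp <- sum(p & !r); tn <- sum(!p & !r)
  conf <- matrix(c(tp, fn, fp, tn), 2, 2,
                 dimnames = list(pred = c("QS", "NONQS"), ref = c("QS", "NONQS")))
  list(confusion = conf,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

# Do two half-open intervals overlap by more than frac of the shorter one?
interval_match <- function(a0, a1, b0, b1, frac) {
  inter <- min(a1, b1) - max(a0, b0)
  inter > frac * min(a1 - a0, b1 - b0)
}

#' Event-level detection and misclassification factors
#'
#' A reference (visual) QS period counts as detected when some predicted
#' period overlaps it by more than `overlap_frac` of the shorter of the two
#' durations; DF is the fraction of reference periods detected. A predicted
#' period matching no reference period under the same rule is a
#' misclassification; MF is the fraction of predictions misclassified.
#'
#' @param pred,ref predicted and reference `hypnogram`s.
#' @param overlap_frac overlap fraction (default 0.5, i.e. ">50%").
#' @return list with `df`, `mf` (NA when the respective denominator is
#'   zero), `n_visual_periods`, `n_detected_periods`.
#' @export
event_metrics <- function(pred, ref, overlap_frac = 0.5) {
  vis <- state_intervals(ref, "QS")
  det <- state_intervals(pred, "QS")
  nv <- nrow(vis); nd <- nrow(det)
  vis_hit <- logical(nv); det_hit <- logical(nd)
  for (i in seq_len(nv)) for (j in seq_len(nd)) {
    if (interval_match(vis$start_s[i], vis$end_s[i],
                       det$start_s[j], det$end_s[j], overlap_frac)) {
      vis_hit[i] <- TRUE; det_hit[j] <- TRUE
    }
  }
  list(df = if (nv > 0) sum(vis_hit) / nv else NA_real_,
       mf = if (nd > 0) sum(!det_hit) / nd else NA_real_,
       n_visual_periods = nv, n_detected_periods = nd)
}

#' Threshold-sweep ROC of an envelope against a reference hypnogram
#'
#' The classification threshold is varied over the percentile grid of the
#' envelope values (which brackets the mean-threshold operating point); per
#' threshold, the raw thresholded indicator (without the 3-minute rule,
#' since only the threshold is being varied) is compared sample-wise to the
#' rasterized reference. AUC by the trapezium rule.
#'
#' @param envelope an `envelope_trace`.
#' @param ref reference `hypnogram` over the same span.
#' @param n_thresholds size of the percentile grid (default 101).
#' @return a `roc_curve`: list with `thresholds`, `fpr`, `tpr`, `auc`
#'   (NA when the reference is single-class), and the mean-threshold
#'   operating point (`op_fpr`, `op_tpr`).
#' @export
roc_curve <- function(envelope, ref, n_thresholds = 101L) {
  n <- length(envelope$values)
  r <- rasterize_hypnogram(ref, 0, n / envelope$fs, envelope$fs)
  m <- min(length(r), n)
  env <- envelope$values[seq_len(m)]; r <- r[seq_len(m)]
  ok <- !is.na(r)
  env <- env[ok]; r <- r[ok]
  thr_mean <- envelope$threshold %||% mean(env)
  thr <- sort(unique(c(stats::quantile(env, probs = seq(0, 1, length.out = n_thresholds),
                                       names = FALSE), thr_mean)))
  pos <- sum(r); neg <- sum(!r)
  # counts above each threshold via one sort + suffix sums
  ord <- order(env)
  env_s <- env[ord]; r_s <- r[ord]
  pos_above <- rev(cumsum(rev(as.numeric(r_s))))        # positives with env >= env_s[i]
  n_s <- length(env_s)
  i_le <- findInterval(thr, env_s)                      # samples with env <= thr
  tp <- ifelse(i_le < n_s, pos_above[i_le + 1L], 0)
  above <- n_s - i_le
  fp <- above - tp
  tpr <- if (pos > 0) tp / pos else rep(NA_real_, length(thr))
  fpr <- if (neg > 0) fp / neg else rep(NA_real_, length(thr))
  degenerate <- pos == 0 || neg == 0
  auc <- if (degenerate) NA_real_ else {
    # threshold-ordered polyline from (0,0) to (1,1)
    o <- order(thr, decreasing = TRUE)
    xx <- c(0, fpr[o], 1); yy <- c(0, tpr[o], 1)
    sum(diff(xx) * (utils::head(yy, -1) + utils::tail(yy, -1)) / 2)
  }
  iop <- which.min(abs(thr - thr_mean))
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc,
                 op_threshold = thr_mean, op_fpr = fpr[iop], op_tpr = tpr[iop]),
            class = "roc_curve")
}

#' Median ROC curve across recordings
#'
#' Each curve's TPR is interpolated onto a common FPR grid (0 to 1 by 0.01),
#' the pointwise median taken, monotonicity enforced (isotonic cleanup), and
#' the AUC of the median curve computed by the trapezium rule.
#'
#' @param curves list of `roc_curve` objects.
#' @return a `roc_curve` on the common FPR grid.
#' @export
median_roc <- function(curves) {
  if (!length(curves)) stop("need at least one ROC curve")
  grid <- seq(0, 1, by = 0.01)
  mat <- vapply(curves, function(cv) {
    o <- order(cv$fpr, cv$tpr)
    x <- c(0, cv$fpr[o], 1); y <- c(0, cv$tpr[o], 1)
    stats::approx(x, y, xout = grid, ties = max, rule = 2)$y
  }, numeric(length(grid)))
  med <- apply(mat, 1L, stats::median)
  med <- cummax(pmin(1, pmax(0, med)))
  structure(list(thresholds = grid, fpr = grid, tpr = med,
                 auc = trapz(grid, med)),
            class = "roc_curve")
}

#' Cohen's kappa between two hypnograms
#'
#' Rasterized at 1 Hz over the common span; kappa = (po - pe) / (1 - pe)
#' with the standard large-sample asymptotic 95% confidence interval.
#'
#' @param rater_a,rater_b `hypnogram`s from two raters.
#' @return list with `kappa` and `ci95` (length-2 vector); both NA when
#'   chance agreement is 1.
#' @export
cohen_kappa <- function(rater_a, rater_b) {
  sa <- hypnogram_span(rater_a); sb <- hypnogram_span(rater_b)
  t0 <- max(sa[1], sb[1]); t1 <- min(sa[2], sb[2])
  if (t1 <= t0) stop("hypnograms do not overlap in time")
  a <- rasterize_hypnogram(rater_a, t0, t1)
  b <- rasterize_hypnogram(rater_b, t0, t1)
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (abs(1 - pe) < 1e-12) return(list(kappa = NA_real_, ci95 = c(NA_real_, NA_real_)))
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  list(kappa = kappa, ci95 = kappa + c(-1.96, 1.96) * se)
}

#' Group per-recording metrics by postmenstrual age
#'
#' Two-week PMA bins (<31, 31-32, 33-34, 35-36, 37-38, >38 weeks; inclusive
#' lower edges) with per-bin median and interquartile range of each metric.
#'
#' @param results data.frame with a `pma_weeks` column plus numeric metric
#'   columns.
#' @return data.frame, one row per (bin, metric): `group`, `metric`, `n`,
#'   `median`, `iqr` (NA for empty bins).
#' @export
grouped_report <- function(results) {
  edges <- c(-Inf, 31, 33, 35, 37, 39, Inf)
  lab <- c("<31", "31-32", "33-34", "35-36", "37-38", ">38")
  bin <- cut(results$pma_weeks, edges, labels = lab, right = FALSE)
  metrics <- setdiff(names(results), c("pma_weeks", "subject_id", "recording_id"))
  out <- do.call(rbind, lapply(lab, function(g) {
    sel <- which(bin == g)
    do.call(rbind, lapply(metrics, function(m) {
      v <- results[[m]][sel]; v <- v[is.finite(v)]
      data.frame(group = g, metric = m, n = length(v),
                 median = if (length(v)) stats::median(v) else NA_real_,
                 iqr = if (length(v)) stats::IQR(v) else NA_real_)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Paired t-test between two algorithm variants
#'
#' Utility for comparing per-recording metric values of two pipeline
#' variants.
#'
#' @param metric_a,metric_b paired per-recording metric vectors.
#' @return `htest` object from [stats::t.test()] with `paired = TRUE`.
#' @export
paired_variant_test <- function(metric_a, metric_b) {
  stats::t.test(metric_a, metric_b, paired = TRUE)
}
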