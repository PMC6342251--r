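# Quiet-sleep-specific maturational features (Burst%, relative band powers)
# and mixed-model trend regression over postmenstrual age.

#' Relative spectral band powers of an epoch
#'
#' Welch-averaged spectrum per channel; band powers in delta (1-3 Hz),
#' theta (3-8 Hz), alpha (8-12 Hz) and beta (12-30 Hz) are divided by the
#' total power over the full processed range (1-40 Hz, the pre-processing
#' passband); channel values are reduced by the median for robustness to
#' channel-specific deviations.
#'
#' @param epoch an `eeg_recording` slice, >= 30 s.
#' @param total_band length-2 vector: the full frequency range (default
#'   `c(1, 40)`).
#' @return named numeric vector `rel_delta`, `rel_theta`, `rel_alpha`,
#'   `rel_beta`, each in `[0, 1]`.
#' @export
relative_band_powers <- function(epoch, total_band = c(1, 40)) {
  if (duration_s(epoch) < 30) stop("epoch too short for band powers (need >= 30 s)")
  bands <- list(rel_delta = c(1, 3), rel_theta = c(3, 8),
                rel_alpha = c(8, 12), rel_beta = c(12, 30))
  per_ch <- apply(epoch$data, 1L, function(x) {
    w <- welch_psd(x, epoch$fs)
    tot <- band_power(w$freq, w$psd, total_band[1], total_band[2])
    vapply(bands, function(b)
      if (tot > 0) band_power(w$freq, w$psd, b[1], b[2]) / tot else NA_real_, 0)
  })
  apply(per_ch, 1L, stats::median)
}

#' Burst percentage of an epoch
#'
#' Fraction of time spent in bursts versus suppressed interburst intervals,
#' from a pluggable burst detector (default: the NLEO/SAT detector of
#' [sat_detect()]); per-channel burst masks are combined here by averaging
#' the channel-mean energy inside the detector, and the percentage taken
#' over the epoch.
#'
#' @param epoch an `eeg_recording` slice, >= 60 s.
#' @param detector function `(eeg_recording) -> logical per-sample burst
#'   mask`; default [sat_detect()].
#' @return scalar percentage in `[0, 100]`.
#' @export
burst_percent <- function(epoch, detector = sat_detect) {
  if (duration_s(epoch) < 60) stop("epoch too short for Burst% (need >= 60 s)")
  mask <- detector(epoch)
  100 * mean(mask)
}

#' Per-recording quiet-sleep characteristics
#'
#' Computes Burst% and relative band powers per QS period (median over
#' channels inside each period), then averages over periods to one value
#' set per recording. `mode = "nonstate"` instead tiles the first
#' `nonstate_hours` of the recording into successive 20 min epochs
#' (the average QS duration) regardless of sleep state.
#'
#' @param rec a band-passed `eeg_recording`.
#' @param hyp a `hypnogram` (detected or visual).
#' @param mode `"qs"` (default) or `"nonstate"`.
#' @param epoch_min nonstate epoch length, minutes (default 20).
#' @param nonstate_hours maximum recording span tiled in nonstate mode
#'   (default 4).
#' @param detector burst detector passed to [burst_percent()].
#' @return one-row data.frame: `burst_pct`, `rel_delta`, `rel_theta`,
#'   `rel_alpha`, `rel_beta`, `n_periods` (all-NA with a warning when no
#'   usable period exists).
#' @export
qs_characteristics <- function(rec, hyp, mode = c("qs", "nonstate"),
                               epoch_min = 20, nonstate_hours = 4,
                               detector = sat_detect) {
  mode <- match.arg(mode)
  if (mode == "qs") {
    per <- state_intervals(hyp, "QS")
    per <- per[per$end_s - per$start_s >= 60, , drop = FALSE]
  } else {
    span <- min(duration_s(rec), nonstate_hours * 3600)
    starts <- seq(0, span - epoch_min * 60, by = epoch_min * 60)
    per <- data.frame(start_s = starts, end_s = starts + epoch_min * 60)
  }
  if (!nrow(per)) {
    warning("no usable periods; returning NA characteristics")
    return(data.frame(burst_pct = NA_real_, rel_delta = NA_real_,
                      rel_theta = NA_real_, rel_alpha = NA_real_,
                      rel_beta = NA_real_, n_periods = 0L))
  }
  vals <- t(vapply(seq_len(nrow(per)), function(i) {
    ep <- slice_recording(rec, per$start_s[i], per$end_s[i])
    c(burst_pct = burst_percent(ep, detector), relative_band_powers(ep))
  }, numeric(5)))
  out <- as.data.frame(t(colMeans(vals)))
  out$n_periods <- nrow(per)
  out
}

# Wald CI helper
wald_ci <- function(b, se) b + c(-1.96, 1.96) * se

#' Fit a maturational trend over postmenstrual age
#'
#' Mixed-effects regression with a subject-level random intercept (REML),
#' linear or quadratic in PMA, optionally on the log of the response. PMA
#' is centered at 34 weeks before squaring to tame collinearity; reported
#' coefficients are back-transformed to the raw-PMA parameterization
#' `y = a + b1 x + b2 x^2`. Wald p-values use Satterthwaite degrees of
#' freedom; singular fits fall back to ordinary least squares with
#' cluster-robust (by subject) standard errors, flagged in the output.
#'
#' @param values per-recording scalar characteristic.
#' @param pma_weeks per-recording postmenstrual age, weeks.
#' @param subject_ids per-recording subject identifier.
#' @param model `"linear"` or `"quadratic"`.
#' @param transform `"identity"` or `"log"` (natural log of the response).
#' @param pma_range keep recordings within this PMA window (default
#'   `c(31, 38)`, the range of reliable detection; `NULL` lifts the
#'   restriction).
#' @param center PMA centering constant, weeks (default 34).
#' @return a `trend_fit`: list with `model`, `transform`, `b` (named
#'   coefficients on the raw-PMA scale), `se`, `ci95` (matrix), `p`,
#'   `n_recordings`, `n_subjects`, `method` (`"lmm"` or `"ols_robust"`).
#' @export
fit_trend <- function(values, pma_weeks, subject_ids,
                      model = c("linear", "quadratic"),
                      transform = c("identity", "log"),
                      pma_range = c(31, 38), center = 34) {
  model <- match.arg(model); transform <- match.arg(transform)
  d <- data.frame(y = as.numeric(values), pma = as.numeric(pma_weeks),
                  subject = as.factor(subject_ids))
  d <- d[is.finite(d$y) & is.finite(d$pma), , drop = FALSE]
  if (!is.null(pma_range))
    d <- d[d$pma >= pma_range[1] & d$pma <= pma_range[2], , drop = FALSE]
  if (nrow(d) < 6L || length(unique(d$subject)) < 3L)
    stop("need at least 6 recordings from at least 3 subjects")
  if (transform == "log") {
    if (any(d$y <= 0)) stop("log transform requires strictly positive values")
    d$y <- log(d$y)
  }
  d$x <- d$pma - center
  d$x2 <- d$x^2
  form <- if (model == "linear") y ~ x + (1 | subject) else y ~ x + x2 + (1 | subject)
  method <- "lmm"
  fit <- tryCatch(
    lmerTest::lmer(form, data = d, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))),
    error = function(e) NULL)
  singular <- is.null(fit) || lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    method <- "ols_robust"
    oform <- if (model == "linear") y ~ x else y ~ x + x2
    ofit <- stats::lm(oform, data = d)
    V <- sandwich::vcovCL(ofit, cluster = d$subject)
    co <- stats::coef(ofit)
    se_all <- sqrt(diag(V))
    z <- co / se_all
    p_all <- 2 * stats::pnorm(-abs(z))
    co_tab <- cbind(Estimate = co, `Std. Error` = se_all, `Pr(>|t|)` = p_all)
    Vfull <- V
  } else {
    co_tab <- stats::coef(summary(fit))
    colnames(co_tab)[colnames(co_tab) == "Pr(>|t|)"] <- "Pr(>|t|)"
    Vfull <- as.matrix(stats::vcov(fit))
  }
  est <- co_tab[, "Estimate"]; se <- co_tab[, "Std. Error"]
  p <- co_tab[, "Pr(>|t|)"]
  if (model == "linear") {
    b <- c(b = unname(est["x"])); bse <- c(b = unname(se["x"]))
    bp <- c(b = unname(p["x"]))
  } else {
    # back-transform centered (x - c) parameterization to raw PMA:
    # b1_raw = b1 - 2 c b2 ; b2_raw = b2
    c_ <- center
    b1 <- est["x"] - 2 * c_ * est["x2"]
    v11 <- Vfull["x", "x"]; v22 <- Vfull["x2", "x2"]; v12 <- Vfull["x", "x2"]
    se1 <- sqrt(v11 + 4 * c_^2 * v22 - 4 * c_ * v12)
    b <- c(b1 = unname(b1), b2 = unname(est["x2"]))
    bse <- c(b1 = unname(se1), b2 = unname(se["x2"]))
    bp <- c(b1 = 2 * stats::pnorm(-abs(b1 / se1)), b2 = unname(p["x2"]))
    names(bp) <- c("b1", "b2")
  }
  ci <- t(vapply(seq_along(b), function(i) wald_ci(b[i], bse[i]), numeric(2)))
  dimnames(ci) <- list(names(b), c("lo", "hi"))
  structure(list(model = model, transform = transform, b = b, se = bse,
                 ci95 = ci, p = bp, n_recordings = nrow(d),
                 n_subjects = length(unique(d$subject)), method = method),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s %s trend (%s), %d recordings / %d subjects\n",
              x$transform, x$model, x$method, x$n_recordings, x$n_subjects))
  for (nm in names(x$b))
    cat(sprintf("  %s = %.4g (SE %.3g, 95%% CI %.4g..%.4g, p = %.3g)\n",
                nm, x$b[nm], x$se[nm], x$ci95[nm, 1], x$ci95[nm, 2], x$p[nm]))
  invisible(x)
}
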