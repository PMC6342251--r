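# Synthetic preterm-EEG simulator with ground-truth hypnograms.
#
# Quiet sleep is emulated as trace-discontinu-like alternation of
# high-amplitude slow-wave bursts and low-amplitude interburst intervals
# (IBIs); non-QS as continuous mixed 1-15 Hz activity; sporadic broadband
# high-power transients emulate movement artifacts. PMA maps monotonically
# to longer IBIs below 31 weeks and to a reduced QS/non-QS amplitude
# contrast above 38 weeks (the near-term continuous EEG). The generator
# reproduces the amplitude-and-slow-frequency signature the detector keys
# on; it makes no claim of physiological waveform realism.

#' Simulation configuration
#'
#' @param pma_weeks postmenstrual age, weeks (default 33).
#' @param duration_s recording length, seconds (default 4 h).
#' @param fs sampling rate, Hz (default 250).
#' @param n_channels number of EEG channels (default 8).
#' @param qs_cycle list: mean/sd of QS and non-QS state durations, seconds
#'   (QS mean 20 min - the average QS duration - non-QS mean 30 min).
#' @param qs_burst list: burst / IBI durations (s) and amplitudes (uV RMS)
#'   inside QS.
#' @param nonqs_amp_uv non-QS amplitude, uV RMS.
#' @param contrast scalar >= 1 scaling QS discontinuity; at 1 the QS signal
#'   is statistically identical to non-QS (uninformative limit), the
#'   default 2 gives the nominal burst/IBI alternation.
#' @param artifact list: `rate_per_hour` (overall transient rate), `dur_s`
#'   (single-transient duration), `amp_gain` (amplitude gain over the
#'   non-QS level), `bout_rate_per_hour` and `bout_dur_s`: transients
#'   cluster inside movement bouts (care / handling episodes), the pattern
#'   that actually disrupts discontinuity-based staging - isolated brief
#'   transients average out under the minutes-long envelope smoothing.
#' @param interchannel_cor shared-source correlation between channels
#'   (default 0.3).
#' @param seed integer seed fixing the full realization.
#' @return a `sim_config` list.
#' @export
sim_config <- function(pma_weeks = 33, duration_s = 4 * 3600, fs = 250,
                       n_channels = 8,
                       qs_cycle = list(qs_mean_s = 1200, qs_sd_s = 240,
                                       nonqs_mean_s = 1800, nonqs_sd_s = 420),
                       qs_burst = list(burst_dur_s = 2, ibi_dur_s = 3,
                                       burst_amp_uv = 50, ibi_amp_uv = 8),
                       nonqs_amp_uv = 20, contrast = 2,
                       artifact = list(rate_per_hour = 10, dur_s = 2,
                                       amp_gain = 20,
                                       bout_rate_per_hour = 2,
                                       bout_dur_s = 120),
                       interchannel_cor = 0.3, seed = 1L) {
  stopifnot(fs > 80, duration_s > 0, n_channels >= 1, contrast >= 1)
  structure(list(pma_weeks = pma_weeks, duration_s = duration_s, fs = fs,
                 n_channels = n_channels, qs_cycle = qs_cycle,
                 qs_burst = qs_burst, nonqs_amp_uv = nonqs_amp_uv,
                 contrast = contrast, artifact = artifact,
                 interchannel_cor = interchannel_cor, seed = as.integer(seed)),
            class = "sim_config")
}

# positive truncated-normal draw(s)
rtnorm <- function(n, mean, sd, min) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < min)
  for (i in bad) {
    repeat { v <- stats::rnorm(1, mean, sd); if (v >= min) break }
    out[i] <- v
  }
  out
}

# band-limited unit-RMS noise
bl_noise <- function(n, fs, lo, hi) {
  x <- signal::filter(signal::butter(2, c(lo, hi) / (fs / 2), type = "pass"),
                      stats::rnorm(n))
  x <- as.numeric(x)
  x / stats::sd(x)
}

#' Simulate one preterm-EEG recording with ground truth
#'
#' @param cfg a [sim_config()].
#' @return list with `recording` (an `eeg_recording`), `hypnogram` (ground
#'   truth) and `artifact_mask` (logical per sample).
#' @export
simulate_recording <- function(cfg) {
  fs <- cfg$fs
  n <- as.integer(round(cfg$duration_s * fs))
  nch <- cfg$n_channels
  pma <- cfg$pma_weeks

  # PMA mapping: longer IBIs below 31 w; reduced contrast above 38 w
  ibi_mult <- 1 + 0.3 * max(0, 31 - pma)
  near_term <- max(0.25, 1 - 0.25 * max(0, pma - 38))
  g <- (cfg$contrast - 1) * near_term        # 0 = QS identical to non-QS
  qb <- cfg$qs_burst
  burst_amp <- cfg$nonqs_amp_uv + g * (qb$burst_amp_uv - cfg$nonqs_amp_uv)
  ibi_amp <- cfg$nonqs_amp_uv + g * (qb$ibi_amp_uv - cfg$nonqs_amp_uv)
  # spectral content weight of the slow (0.5-3 Hz) source
  w_nonqs <- 0.4
  w_burst <- w_nonqs + g * (0.85 - w_nonqs)

  # --- state sequence -------------------------------------------------
  states <- with_seed(child_seed(cfg$seed, "states"), {
    qc <- cfg$qs_cycle
    st <- list(); t <- 0; s <- "NONQS"
    while (t < cfg$duration_s) {
      dur <- if (s == "QS") rtnorm(1, qc$qs_mean_s, qc$qs_sd_s, 300)
             else rtnorm(1, qc$nonqs_mean_s, qc$nonqs_sd_s, 420)
      st[[length(st) + 1L]] <- c(t, min(t + dur, cfg$duration_s),
                                 if (s == "QS") 1 else 0)
      t <- t + dur
      s <- if (s == "QS") "NONQS" else "QS"
    }
    do.call(rbind, st)
  })
  hyp <- hypnogram(states[, 1], states[, 2],
                   ifelse(states[, 3] == 1, "QS", "NONQS"))

  # --- amplitude envelope and slow-content weight ---------------------
  env <- rep(cfg$nonqs_amp_uv, n)
  wsl <- rep(w_nonqs, n)
  with_seed(child_seed(cfg$seed, "bursts"), {
    for (r in which(states[, 3] == 1)) {
      i0 <- as.integer(states[r, 1] * fs) + 1L
      i1 <- min(n, as.integer(states[r, 2] * fs))
      t <- i0
      burst <- TRUE
      while (t <= i1) {
        dur <- if (burst) rtnorm(1, qb$burst_dur_s, 0.3 * qb$burst_dur_s,
                                 0.4 * qb$burst_dur_s)
               else rtnorm(1, qb$ibi_dur_s * ibi_mult,
                           0.3 * qb$ibi_dur_s * ibi_mult,
                           0.4 * qb$ibi_dur_s * ibi_mult)
        t2 <- min(i1, t + as.integer(round(dur * fs)) - 1L)
        env[t:t2] <- if (burst) burst_amp else ibi_amp
        wsl[t:t2] <- if (burst) w_burst else w_nonqs
        t <- t2 + 1L
        burst <- !burst
      }
    }
  })
  # soften envelope transitions over ~0.2 s (no hard clicks)
  env <- ma_reflect(env, as.integer(0.2 * fs))
  wsl <- ma_reflect(wsl, as.integer(0.2 * fs))
  wfa <- sqrt(pmax(0, 1 - wsl^2))

  # --- waveforms: shared + independent band-limited sources -----------
  rho <- cfg$interchannel_cor
  X <- matrix(0, nch, n)
  with_seed(child_seed(cfg$seed, "waves"), {
    c_slow <- bl_noise(n, fs, 0.5, 3)
    c_fast <- bl_noise(n, fs, 1, 15)
    for (ch in seq_len(nch)) {
      o_slow <- bl_noise(n, fs, 0.5, 3)
      o_fast <- bl_noise(n, fs, 1, 15)
      slow <- sqrt(rho) * c_slow + sqrt(1 - rho) * o_slow
      fast <- sqrt(rho) * c_fast + sqrt(1 - rho) * o_fast
      X[ch, ] <- env * (wsl * slow + wfa * fast)
    }
  })

  # --- movement artifacts ---------------------------------------------
  amask <- logical(n)
  with_seed(child_seed(cfg$seed, "artifacts"), {
    hours <- cfg$duration_s / 3600
    n_art <- stats::rpois(1, cfg$artifact$rate_per_hour * hours)
    bout_rate <- cfg$artifact$bout_rate_per_hour %||% 2
    bout_dur <- cfg$artifact$bout_dur_s %||% 120
    n_bouts <- max(1L, stats::rpois(1, bout_rate * hours))
    bout_t0 <- stats::runif(n_bouts, 0, max(0, cfg$duration_s - bout_dur))
    if (n_art > 0) {
      amp <- cfg$artifact$amp_gain * cfg$nonqs_amp_uv
      for (a in seq_len(n_art)) {
        b <- sample.int(n_bouts, 1L)
        t0 <- bout_t0[b] +
          stats::runif(1, 0, max(1e-3, bout_dur - cfg$artifact$dur_s))
        i0 <- as.integer(t0 * fs) + 1L
        i1 <- min(n, i0 + as.integer(cfg$artifact$dur_s * fs) - 1L)
        chans <- which(stats::runif(nch) < 0.5)
        if (!length(chans)) chans <- sample.int(nch, 1L)
        burst_noise <- bl_noise(i1 - i0 + 1L + 2L * fs, fs, 1, 40)
        taper <- stats::dnorm(seq(-2, 2, length.out = i1 - i0 + 1L)) / stats::dnorm(0)
        for (ch in chans)
          X[ch, i0:i1] <- X[ch, i0:i1] +
            amp * taper * burst_noise[fs + seq_len(i1 - i0 + 1L)]
        amask[i0:i1] <- TRUE
      }
    }
  })

  rec <- eeg_recording(X, fs, sprintf("SIM%d", seq_len(nch)), pma,
                       meta = list(simulated = TRUE, config = unclass(cfg)))
  list(recording = rec, hypnogram = hyp, artifact_mask = amask)
}

#' Simulate a longitudinal cohort of EEG recordings
#'
#' Subjects are assigned evenly spaced ages across `pma_range` with 2-3
#' week revisit spacing; per-subject random intercepts perturb the
#' burst-amplitude and burst-duration generator parameters so that
#' subject-level clustering is present in downstream features.
#'
#' @param n_subjects number of subjects.
#' @param recordings_per_subject recordings per subject (scalar or range).
#' @param pma_range PMA span, weeks (default `c(27, 42)`).
#' @param duration_s per-recording duration (default 1 h; EEG cohorts are
#'   heavy - see [simulate_trend_data()] for feature-level cohorts).
#' @param seed master seed.
#' @param ... overrides passed to [sim_config()].
#' @return list of lists with `recording`, `hypnogram`, `artifact_mask`,
#'   `subject_id`, `pma_weeks`.
#' @export
simulate_cohort <- function(n_subjects, recordings_per_subject = 2,
                            pma_range = c(27, 42), duration_s = 3600,
                            seed = 1L, ...) {
  rng <- range(recordings_per_subject)
  out <- list()
  with_seed(child_seed(seed, "cohort"), {
    for (s in seq_len(n_subjects)) {
      nrec <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
      start <- stats::runif(1, pma_range[1], max(pma_range[1],
                                                 pma_range[2] - 2.5 * (nrec - 1)))
      amp_mult <- exp(stats::rnorm(1, 0, 0.1))
      dur_mult <- exp(stats::rnorm(1, 0, 0.1))
      for (r in seq_len(nrec)) {
        pma <- min(pma_range[2], start + (r - 1) * stats::runif(1, 2, 3))
        cfg <- sim_config(pma_weeks = pma, duration_s = duration_s,
                          seed = child_seed(seed, sprintf("s%dr%d", s, r)), ...)
        cfg$qs_burst$burst_amp_uv <- cfg$qs_burst$burst_amp_uv * amp_mult
        cfg$qs_burst$burst_dur_s <- cfg$qs_burst$burst_dur_s * dur_mult
        sim <- simulate_recording(cfg)
        sim$subject_id <- sprintf("S%02d", s)
        sim$pma_weeks <- pma
        out[[length(out) + 1L]] <- sim
      }
    }
  })
  out
}

#' Simulate a feature-level maturation cohort
#'
#' Draws per-recording characteristic values directly from the trend model
#' `y = a + b1 PMA + b2 PMA^2 + u_subject + eps` (with
#' `u ~ N(0, intercept_sd^2)`, `eps ~ N(0, resid_sd^2)`), the design used
#' to validate [fit_trend()] parameter recovery at scale.
#'
#' @param n_subjects,recordings_per_subject cohort design (range allowed).
#' @param pma_range PMA span, weeks.
#' @param intercept population intercept `a`.
#' @param slope linear coefficient `b1` (per week).
#' @param quad quadratic coefficient `b2` (default 0).
#' @param intercept_sd subject random-intercept SD.
#' @param resid_sd residual SD.
#' @param seed RNG seed.
#' @return data.frame with `subject_id`, `pma_weeks`, `y`.
#' @export
simulate_trend_data <- function(n_subjects = 20, recordings_per_subject = c(2, 3),
                                pma_range = c(31, 38), intercept = 0,
                                slope = 0.045, quad = 0, intercept_sd = 0.1,
                                resid_sd = 0.1, seed = 1L) {
  rng <- range(recordings_per_subject)
  with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      nrec <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
      u <- stats::rnorm(1, 0, intercept_sd)
      pma <- sort(stats::runif(nrec, pma_range[1], pma_range[2]))
      y <- intercept + slope * pma + quad * pma^2 + u +
        stats::rnorm(nrec, 0, resid_sd)
      rows[[s]] <- data.frame(subject_id = sprintf("S%02d", s),
                              pma_weeks = pma, y = y)
    }
    do.call(rbind, rows)
  })
}
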