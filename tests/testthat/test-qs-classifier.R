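# Envelope construction and QS interval extraction.

mk_profile <- function(mat, k = 12L) {
  structure(list(labels = mat, k = k), class = "cluster_profile")
}

test_that("profile averaging is the per-sample channel mean", {
  prof <- mk_profile(rbind(rep(2L, 100), rep(4L, 100)))
  expect_equal(average_profile(prof), rep(3, 100))
  single <- mk_profile(matrix(5L, 1, 50))
  expect_equal(average_profile(single), rep(5, 50))
  set.seed(1)
  m <- matrix(sample(1:12, 300, TRUE), 3, 100)
  avg <- average_profile(mk_profile(m))
  expect_true(all(avg >= apply(m, 2, min) & avg <= apply(m, 2, max)))
})

test_that("de-trending suppresses slow trends and keeps spikes", {
  expect_equal(detrend_square(rep(7, 1000)), rep(0, 1000))
  set.seed(2)
  y <- detrend_square(runif(2000, 1, 12), 500)
  expect_true(all(y >= 0))
  ramp <- seq(0, 1, length.out = 5000)
  spike <- ramp; spike[2500] <- spike[2500] + 5
  out <- detrend_square(spike, 500)
  baseline <- max(detrend_square(ramp, 500))
  expect_lt(baseline, 0.01 * out[2500])
})

test_that("envelope smoothing is a mean-preserving moving average", {
  env <- smooth_envelope(rep(4, 1000), fs = 10, smooth_win_length = 100)
  expect_equal(env$values, rep(4, 1000))
  imp <- numeric(5000); imp[2500] <- 1
  expect_warning(e2 <- smooth_envelope(imp, 10, smooth_win_length = 6000),
                 "shrunk")
  e3 <- smooth_envelope(imp, 10, smooth_win_length = 1000)
  expect_equal(max(e3$values), 1 / 1000, tolerance = 1e-12)
  expect_lte(max(e3$values), max(imp))
})

test_that("stitching processes 2 h blocks with one global mean threshold", {
  fs <- 1
  set.seed(3)
  prof <- mk_profile(matrix(sample(1:12, 4 * 7200, TRUE), 1))   # 4 h at 1 Hz
  res <- stitch_and_threshold(prof, fs, avg_win_length = 100,
                              smooth_win_length = 600)
  expect_equal(length(res$envelope$values), 4 * 7200)
  expect_equal(res$envelope$block_edges, c(7200L, 14400L, 21600L))
  expect_equal(res$envelope$threshold, mean(res$envelope$values))
  const <- mk_profile(matrix(5L, 2, 7200))
  rc <- stitch_and_threshold(const, fs)
  expect_true(all(!rc$indicator))                    # strict >
})

test_that("high-fluctuation epochs rise above the global threshold", {
  fs <- 1
  set.seed(4)
  n <- 4 * 3600
  base <- rep(4L, n)
  planted <- list(c(1000, 1800), c(6000, 7200), c(11000, 12400))
  for (p in planted) {
    idx <- p[1]:p[2]
    base[idx] <- sample(c(1L, 12L), length(idx), TRUE)   # strong fluctuation
  }
  prof <- mk_profile(matrix(base, 1))
  res <- stitch_and_threshold(prof, fs, avg_win_length = 50,
                              smooth_win_length = 300)
  runs <- classqs:::true_runs(res$indicator)
  expect_equal(nrow(runs), 3L)
  for (i in 1:3) {
    expect_lt(runs[i, "start"], planted[[i]][2])
    expect_gt(runs[i, "end"], planted[[i]][1])
  }
})

test_that("the 3-minute rule removes short detections", {
  fs <- 1
  mk_ind <- function(spans, n = 3600) {
    ind <- logical(n)
    for (s in spans) ind[(s[1] + 1):s[2]] <- TRUE
    ind
  }
  h1 <- postprocess_min_duration(mk_ind(list(c(100, 220))), fs)   # 120 s
  expect_true(all(h1$state == "NONQS"))
  h2 <- postprocess_min_duration(mk_ind(list(c(100, 300))), fs)   # 200 s
  expect_equal(sum(h2$state == "QS"), 1L)
  h3 <- postprocess_min_duration(mk_ind(list(c(100, 270), c(1000, 1190))), fs)
  qs <- state_intervals(h3, "QS")
  expect_equal(nrow(qs), 1L)
  expect_equal(qs$start_s, 1000)
  expect_equal(qs$end_s, 1190)
  # output always tiles [0, n)
  expect_equal(attr(h3, "duration_s"), 3600)
})

test_that("adding a constant to the profile leaves the hypnogram unchanged", {
  fs <- 1
  set.seed(5)
  base <- matrix(sample(1:8, 2 * 7200, TRUE), 2)
  p1 <- mk_profile(base)
  p2 <- mk_profile(base + 4L)
  r1 <- stitch_and_threshold(p1, fs, 100, 600)
  r2 <- stitch_and_threshold(p2, fs, 100, 600)
  expect_equal(r1$indicator, r2$indicator)
})

test_that("the full pipeline detects planted QS and degrades gracefully", {
  cfg <- sim_config(duration_s = 2400, fs = 100, n_channels = 3,
                    qs_cycle = list(qs_mean_s = 420, qs_sd_s = 60,
                                    nonqs_mean_s = 500, nonqs_sd_s = 60),
                    artifact = list(rate_per_hour = 0, dur_s = 2, amp_gain = 20),
                    seed = 21)
  sim <- simulate_recording(cfg)
  config <- default_config(notch_hz = NULL, smooth_win_length = 6000L,
                           calibration_s = 30, seed = 9)
  res <- run_class(sim$recording, config)
  qs_frac <- sum(res$hypnogram$end_s[res$hypnogram$state == "QS"] -
                 res$hypnogram$start_s[res$hypnogram$state == "QS"]) /
    attr(res$hypnogram, "duration_s")
  truth_frac <- sum(sim$hypnogram$end_s[sim$hypnogram$state == "QS"] -
                    sim$hypnogram$start_s[sim$hypnogram$state == "QS"]) /
    attr(sim$hypnogram, "duration_s")
  expect_gt(qs_frac, truth_frac - 0.15)
  expect_lt(qs_frac, truth_frac + 0.15)
  qs <- state_intervals(res$hypnogram, "QS")
  expect_true(all(qs$end_s - qs$start_s >= 180))
  # without artifacts, the no-ASR variant agrees closely with the full one
  res_no <- run_class(sim$recording, config, variant = "no_asr")
  sw <- samplewise_agreement(res_no$hypnogram, res$hypnogram)
  acc <- sum(diag(sw$confusion)) / sum(sw$confusion)
  expect_gt(acc, 0.9)
  # stage-named failure for degenerate input
  expect_error(run_class(eeg_recording(matrix(NaN, 2, 1000), 100),
                         default_config()), "preprocess")
})

test_that("stronger QS contrast never reduces sensitivity", {
  sens <- vapply(c(1.2, 1.6, 2.0), function(ctr) {
    cfg <- sim_config(duration_s = 3600, fs = 100, n_channels = 4,
                      contrast = ctr,
                      qs_cycle = list(qs_mean_s = 600, qs_sd_s = 100,
                                      nonqs_mean_s = 700, nonqs_sd_s = 120),
                      artifact = list(rate_per_hour = 0, dur_s = 2, amp_gain = 20),
                      seed = 31)
    sim <- simulate_recording(cfg)
    res <- run_class(sim$recording,
                     default_config(notch_hz = NULL, smooth_win_length = 12000L,
                                    seed = 9),
                     keep_diagnostics = FALSE)
    samplewise_agreement(res$hypnogram, sim$hypnogram)$sensitivity
  }, 0)
  expect_true(all(diff(sens) >= -1e-9))
})
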