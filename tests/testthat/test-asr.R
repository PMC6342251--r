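# Artifact subspace reconstruction.

test_that("geometric-median covariance handles degenerate and robust cases", {
  x <- c(1, 2, -1)
  expect_equal(geometric_median_covariance(matrix(x, 3, 1)), tcrossprod(x),
               tolerance = 1e-8)
  v <- c(2, -1, 0.5)
  expect_equal(geometric_median_covariance(cbind(v, -v)), tcrossprod(v),
               tolerance = 1e-8)
})

test_that("geometric-median covariance resists outliers that inflate the mean", {
  set.seed(42)
  clean <- matrix(rnorm(3 * 200), 3, 200)
  outl <- 100 * matrix(rnorm(3 * 5), 3, 5)
  X <- cbind(clean, outl)
  Y_med <- geometric_median_covariance(X)
  Y_med_clean <- geometric_median_covariance(clean)
  Y_clean <- tcrossprod(clean) / 200            # mean covariance of clean part
  Y_mean <- tcrossprod(X) / ncol(X)
  fro <- function(A) sqrt(sum(A^2))
  # 2.5% contamination at x100 barely moves the geometric median ...
  expect_lt(fro(Y_med - Y_med_clean) / fro(Y_med_clean), 0.15)
  # ... while the mean covariance explodes
  expect_gt(fro(Y_mean) / fro(Y_clean), 10)
  expect_lt(fro(Y_med - Y_clean) / fro(Y_clean), 1)
})

test_that("calibration thresholds follow t_c = mu_c + asr_thresh * sigma_c", {
  expect_equal(formals(asr_calibrate)$asr_thresh, 10)   # tuned default
  set.seed(3)
  calib <- eeg_recording(matrix(rnorm(2 * 250 * 60), 2), 250)
  m <- asr_calibrate(calib)
  expect_s3_class(m, "asr_model")
  expect_true(all(diag(m$T) > 0))
  expect_equal(crossprod(m$V_Y), diag(2), tolerance = 1e-8)
  expect_equal(m$M %*% t(m$M), m$Y, tolerance = 1e-8)
  # white noise: component RMS ~ sigma with narrow spread -> t_c above mean
  comps <- t(m$V_Y) %*% calib$data
  for (c_ in 1:2) {
    r <- classqs:::segment_rms(comps[c_, ], 125, 0.66)
    expect_gt(m$T[c_, c_], mean(r))
    expect_lt(m$T[c_, c_], mean(r) + 10 * sd(r) * 1.5)
  }
})

test_that("a near-deterministic component has a tight threshold", {
  fs <- 250
  t <- seq_len(fs * 60) / fs
  set.seed(4)
  X <- rbind(10 * sin(2 * pi * 5 * t), rnorm(length(t)))
  m <- asr_calibrate(eeg_recording(X, fs))
  comps <- t(m$V_Y) %*% X
  # component carrying the sine: 0.5 s windowed RMS is nearly constant
  i <- which.max(abs(m$V_Y[1, ]))
  r <- classqs:::segment_rms(comps[i, ], 125, 0.66)
  expect_lt(m$T[i, i], mean(r) + 10 * sd(r) + 1e-6)
  expect_equal(m$T[i, i], mean(r), tolerance = 0.2)
})

test_that("rank-deficient calibration names the degenerate channel", {
  set.seed(5)
  x <- rnorm(250 * 60)
  X <- rbind(x, x)                         # duplicated channel -> rank 1
  expect_error(asr_calibrate(eeg_recording(X, 250, c("C3", "C4"))),
               "rank-deficient")
})

test_that("window decomposition keeps calibration-like data, rejects inflation", {
  set.seed(6)
  calib <- eeg_recording(matrix(rnorm(3 * 250 * 60), 3), 250)
  m <- asr_calibrate(calib)
  S <- matrix(rnorm(3 * 500), 3)
  dec <- window_decomposition(S, m)
  expect_true(all(dec$keep))
  expect_true(all(dec$A == 1))
  S_bad <- S; S_bad[2, ] <- S_bad[2, ] * 1000
  dec_bad <- window_decomposition(S_bad, m)
  expect_true(any(!dec_bad$keep))
  # projection back through the calibration basis is the identity on T
  expect_equal(m$T %*% t(m$V_Y) %*% m$V_Y, m$T, tolerance = 1e-10)
})

test_that("reconstruction matrix matches the hand-assembled SVD oracle", {
  set.seed(7)
  calib <- eeg_recording(matrix(rnorm(3 * 250 * 60), 3), 250)
  m <- asr_calibrate(calib)
  for (rep in 1:20) {
    S <- matrix(rnorm(3 * 10), 3)
    S[1, ] <- S[1, ] * sample(c(1, 1000), 1)
    dec <- window_decomposition(S, m)
    R <- reconstruction_matrix(dec, m)
    R_oracle <- oracle_reconstruction(dec$V, dec$A, m$M)
    expect_lt(max(abs(R - R_oracle)), 1e-10)
  }
})

test_that("reconstruction is identity with no rejection, zero with full rejection", {
  set.seed(8)
  calib <- eeg_recording(matrix(rnorm(3 * 250 * 60), 3), 250)
  m <- asr_calibrate(calib)
  S <- matrix(rnorm(3 * 100), 3)
  dec <- window_decomposition(S, m)
  dec$A <- matrix(1, 3, 3)
  expect_equal(reconstruction_matrix(dec, m), diag(3), tolerance = 1e-8)
  dec$A <- matrix(0, 3, 3)
  expect_equal(reconstruction_matrix(dec, m), matrix(0, 3, 3), tolerance = 1e-12)
  # single rejected component: output has no energy along it
  dec <- window_decomposition(S, m)
  dec$A <- matrix(1, 3, 3); dec$A[2, ] <- 0
  R <- reconstruction_matrix(dec, m)
  # the rejected eigendirection is annihilated: its content never reaches
  # the reconstruction
  expect_lt(max(abs(R %*% dec$V[, 2])), 1e-8)
  # kept directions pass through unchanged up to the subspace interpolation
  s <- S[, 5]
  s_kept <- s - dec$V[, 2] * drop(crossprod(dec$V[, 2], s))
  expect_equal(R %*% s, R %*% s_kept, tolerance = 1e-10)
})

test_that("cleaning is near identity on artifact-free data and removes artifacts", {
  set.seed(9)
  fs <- 250
  n <- fs * 120
  X <- matrix(rnorm(4 * n), 4)
  rec <- eeg_recording(X, fs)
  m <- asr_calibrate(slice_recording(rec, 0, 60))
  out <- asr_clean(rec, m, stride_samples = 25L)
  rel <- sqrt(mean((out$data - X)^2)) / sqrt(mean(X^2))
  expect_lt(rel, 0.05)

  # inject 10 broadband x20 artifacts of 2 s
  Xa <- X
  art <- logical(n)
  starts <- seq(65, 115, length.out = 10) * fs
  for (s in starts) {
    idx <- s:(s + 2 * fs)
    Xa[, idx] <- Xa[, idx] + 20 * matrix(rnorm(4 * length(idx)), 4)
    art[idx] <- TRUE
  }
  reca <- eeg_recording(Xa, fs)
  outa <- asr_clean(reca, m, stride_samples = 5L)
  rms <- function(M, sel) sqrt(mean(M[, sel]^2))
  expect_lt(rms(outa$data, art) / rms(Xa, art), 0.5)       # >= 50% reduction
  clean_sel <- !art & seq_len(n) > 2 * fs
  expect_lt(abs(rms(outa$data, clean_sel) / rms(Xa, clean_sel) - 1), 0.10)
  # zero input -> zero output
  z <- eeg_recording(matrix(0, 4, 1000), fs)
  expect_true(all(asr_clean(z, m)$data == 0))
  expect_error(asr_clean(eeg_recording(matrix(0, 2, 100), fs), m), "channels")
})

test_that("cleaning never inflates per-window variance", {
  set.seed(10)
  fs <- 250
  X <- matrix(rnorm(3 * fs * 70), 3)
  X[, 15000:15500] <- X[, 15000:15500] * 30
  rec <- eeg_recording(X, fs)
  m <- asr_calibrate(slice_recording(rec, 0, 55))
  out <- asr_clean(rec, m, stride_samples = 50L)
  w <- fs                                     # 1 s windows
  for (s in seq(1, ncol(X) - w, by = w)) {
    expect_lte(var(as.vector(out$data[, s:(s + w - 1)])),
               var(as.vector(X[, s:(s + w - 1)])) + 1e-6)
  }
})

test_that("calibration epochs avoid artifact-contaminated stretches", {
  set.seed(11)
  fs <- 100
  n <- fs * 600
  X <- matrix(rnorm(2 * n), 2)
  # artifact-dense second half: a 2 s x30 burst every 20 s
  art_starts <- seq(310, 580, by = 20)
  for (t0 in art_starts) {
    idx <- (t0 * fs):((t0 + 2) * fs)
    X[, idx] <- X[, idx] + 30 * matrix(rnorm(2 * length(idx)), 2)
  }
  rec <- eeg_recording(X, fs)
  ep <- select_calibration(rec, 60)
  s0 <- attr(ep, "calibration_start_s")
  # selected epoch overlaps no artifact
  expect_true(all(art_starts + 2 <= s0 | art_starts >= s0 + 60))
  man <- select_calibration(rec, 60, start_s = 0)
  expect_equal(attr(man, "calibration_start_s"), 0)
  expect_equal(ncol(man$data), 60 * fs)
  short <- eeg_recording(matrix(rnorm(2 * 30 * fs), 2), fs)
  expect_error(select_calibration(short, 60), "shorter")
})
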